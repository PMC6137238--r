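#' Default synthetic-cohort parameters calibrated to the study
#'
#' Returns generator parameters whose expected cohort statistics match the
#' published cohort at n = 41: QOL-category probabilities (1, 20, 12, 8)/41,
#' severity probabilities (1, 7, 14, 7, 12)/41, per-ego alter counts on
#' 1..11 with QOL-dependent means averaging about 4.5, nomination propensities
#' dominated by GP / pharmacist / own experience, own-experience placements
#' almost entirely on Circle One, and an HCP nomination propensity that rises
#' with QOL impact (`hcp_gradient`).
#'
#' @param n_participants Cohort size (default 41).
#' @param seed Integer seed (default 1).
#' @return Object of class `ar_sim_params`.
#' @export
default_study_params <- function(n_participants = 41, seed = 1) {
  tax <- alter_taxonomy()
  nomination <- c(
    gp = 1.00, pharmacist = 0.80, own_experience = 0.80,
    friends_colleagues = 0.45, parents_partner = 0.45, internet = 0.40,
    family = 0.35, media = 0.30, allergist_immunologist = 0.20,
    alternative_therapist = 0.20, ent_specialist = 0.15,
    respiratory_specialist = 0.15, practice_nurse = 0.12, other_hcp = 0.10
  )
  circle_probs <- rbind(
    gp                     = c(0.45, 0.25, 0.18, 0.12),
    pharmacist             = c(0.30, 0.30, 0.22, 0.18),
    own_experience         = c(0.95, 0.03, 0.01, 0.01),
    allergist_immunologist = c(0.40, 0.30, 0.20, 0.10),
    respiratory_specialist = c(0.40, 0.30, 0.20, 0.10),
    ent_specialist         = c(0.40, 0.30, 0.20, 0.10),
    other_hcp              = c(0.35, 0.30, 0.20, 0.15),
    practice_nurse         = c(0.15, 0.30, 0.30, 0.25),
    parents_partner        = c(0.25, 0.30, 0.25, 0.20),
    family                 = c(0.15, 0.25, 0.30, 0.30),
    friends_colleagues     = c(0.10, 0.25, 0.30, 0.35),
    internet               = c(0.15, 0.25, 0.30, 0.30),
    media                  = c(0.05, 0.15, 0.35, 0.45),
    alternative_therapist  = c(0.20, 0.30, 0.25, 0.25)
  )
  params <- list(
    n_participants = n_participants,
    qol_probs = stats::setNames(c(1, 20, 12, 8) / 41, qol_levels()),
    severity_probs = stats::setNames(c(1, 7, 14, 7, 12) / 41,
                                     severity_levels()),
    # mean alter-network size per QOL category; weighted average ~4.5,
    # increasing with impairment as observed
    size_means = stats::setNames(c(2, 3.5, 5, 6.5), qol_levels()),
    max_alters = 11,
    nomination_probs = nomination / sum(nomination),
    circle_probs = circle_probs[tax$code, , drop = FALSE],
    hcp_gradient = 1.35,
    n_items = 14,
    prop_female = 0.67,
    prop_metro = 34 / 41,
    seed = seed
  )
  validate_sim_params(structure(params, class = "ar_sim_params"))
}

validate_sim_params <- function(params) {
  stopifnot(inherits(params, "ar_sim_params"))
  with(params, {
    if (!is.numeric(n_participants) || n_participants < 1) {
      stop("n_participants must be >= 1", call. = FALSE)
    }
    for (p in list(qol_probs, severity_probs, nomination_probs)) {
      if (any(p < 0) || abs(sum(p) - 1) > 1e-8) {
        stop("probability vectors must be non-negative and sum to 1",
             call. = FALSE)
      }
    }
    if (any(abs(rowSums(circle_probs) - 1) > 1e-8)) {
      stop("each row of circle_probs must sum to 1", call. = FALSE)
    }
    if (max_alters < 1 || max_alters > length(nomination_probs)) {
      stop("max_alters must lie in 1..number of alter categories",
           call. = FALSE)
    }
    if (hcp_gradient <= 0) stop("hcp_gradient must be positive",
                                call. = FALSE)
  })
  params
}

# shifted truncated Poisson on 1..max: 1 + Pois(mean - 1) conditioned <= max-1
draw_network_size <- function(n, mean, max) {
  lambda <- max(mean - 1, 0.1)
  probs <- stats::dpois(0:(max - 1), lambda)
  1L + sample.int(max, n, replace = TRUE, prob = probs) - 1L
}

# integer mini-RQLQ items whose mean falls in the target QOL bin
draw_rqlq_items <- function(qol, n_items, breaks = c(2, 4)) {
  bounds <- switch(qol,
    QOL_ZERO = c(0, 0),
    QOL_MILD = c(0, breaks[1]),
    QOL_MOD = c(breaks[1], breaks[2]),
    QOL_SEV = c(breaks[2], 6)
  )
  if (qol == "QOL_ZERO") return(rep(0L, n_items))
  target <- stats::runif(1, bounds[1] + 0.25, bounds[2] - 0.25)
  for (i in 1:50) {
    items <- stats::rbinom(n_items, 6, target / 6)
    m <- mean(items)
    if (m > bounds[1] && m <= bounds[2]) return(items)
  }
  rep(as.integer(ceiling(bounds[1]) + 1), n_items)  # degenerate fallback
}

#' Generate a synthetic cohort table
#'
#' Draws, for each ego: a QOL category, a severity response (independent of
#' QOL — the study reports only discordant marginals), an alter-network size
#' from the QOL-conditioned shifted truncated Poisson, a without-replacement
#' alter subset weighted by the nomination propensities (HCP propensities
#' multiplied by `hcp_gradient^(q-1)` where q is the 1-based QOL ordinal), a
#' circle per alter from the per-alter circle distribution, mini-RQLQ items
#' whose mean falls inside the drawn QOL bin, and marginal demographics.
#' Fully reproducible from `params$seed`.
#'
#' @param params An `ar_sim_params`, e.g. [default_study_params()].
#' @return A long-format cohort data.frame in the [read_cohort_table()]
#'   dialect (one row per placement).
#' @export
#' @examples
#' tab <- generate_cohort(default_study_params(seed = 7))
#' cohort <- cohort_from_table(tab)
generate_cohort <- function(params) {
  params <- validate_sim_params(params)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(params$seed)

  tax <- alter_taxonomy()
  hcp <- tax$code[tax$group == "HCP"]
  responses <- severity_responses()
  n <- params$n_participants
  qol <- sample(qol_levels(), n, replace = TRUE, prob = params$qol_probs)
  sev <- sample(responses$response, n, replace = TRUE,
                prob = params$severity_probs)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    q_ord <- match(qol[i], qol_levels())
    k <- draw_network_size(1, params$size_means[[qol[i]]], params$max_alters)
    w <- params$nomination_probs
    w[hcp] <- w[hcp] * params$hcp_gradient^(q_ord - 1)
    alters <- sample(names(w), k, prob = w)
    circles <- vapply(alters, function(a) {
      sample.int(4, 1, prob = params$circle_probs[a, ])
    }, integer(1))
    items <- draw_rqlq_items(qol[i], params$n_items)
    age <- min(86, max(18, round(stats::rlnorm(1, log(38), 0.35))))
    rows[[i]] <- data.frame(
      participant_id = sprintf("P%03d", i),
      age = age,
      sex = if (stats::runif(1) < params$prop_female) "female" else "male",
      region = if (stats::runif(1) < params$prop_metro) "metro" else
        "regional",
      severity_response = sev[i],
      rqlq_items = paste(items, collapse = ";"),
      rqlq_mean = mean(items),
      alter_label = alters,
      circle = as.integer(circles),
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Recover generator parameters from a cohort by direct tabulation
#'
#' Empirical estimates of the quantities the generator parameterises:
#' QOL-category frequencies, per-alter nomination frequency (share of egos
#' nominating each category), per-alter circle distributions, mean network
#' size per QOL category, and the HCP share of network alter density per QOL
#' subgroup. Used to assert generator/estimator consistency.
#'
#' @param cohort An `ar_cohort`, `ar_cohort_network`, or a cohort table
#'   data.frame.
#' @param taxonomy An [alter_taxonomy()].
#' @return List with elements `qol_freq`, `nomination_freq`, `circle_dist`,
#'   `size_mean_by_qol`, `hcp_share_by_qol`.
#' @export
recover_parameters <- function(cohort, taxonomy = alter_taxonomy()) {
  if (is.data.frame(cohort)) cohort <- cohort_from_table(cohort, taxonomy)
  net <- if (inherits(cohort, "ar_cohort_network")) cohort else
    aggregate_cohort(cohort)
  egos <- net$egos
  n <- length(egos)
  qol <- vapply(egos, function(p) p$qol, character(1))
  qol_freq <- vapply(qol_levels(), function(q) mean(qol == q), numeric(1))
  pl <- cohort_placements(egos)
  nomination_freq <- vapply(taxonomy$code,
                            function(a) sum(pl$alter == a) / n, numeric(1))
  circle_dist <- t(vapply(taxonomy$code, function(a) {
    cc <- pl$circle[pl$alter == a]
    if (!length(cc)) return(rep(NA_real_, net$n_circles))
    vapply(seq_len(net$n_circles), function(k) mean(cc == k), numeric(1))
  }, numeric(net$n_circles)))
  sizes <- vapply(egos, function(p) nrow(p$placements), integer(1))
  size_mean_by_qol <- vapply(qol_levels(), function(q) {
    if (!any(qol == q)) return(NA_real_)
    mean(sizes[qol == q])
  }, numeric(1))
  hcp_share_by_qol <- vapply(qol_levels(), function(q) {
    sub <- filter_by_qol(net, q)
    if (length(sub$egos) == 0) return(NA_real_)
    hcp_density_share(network_alter_density(sub), taxonomy)
  }, numeric(1))
  list(qol_freq = qol_freq, nomination_freq = nomination_freq,
       circle_dist = circle_dist, size_mean_by_qol = size_mean_by_qol,
       hcp_share_by_qol = hcp_share_by_qol)
}
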