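#' Build one ego network from a participant record
#'
#' Validates and assembles a single participant ("ego"): scores the two
#' instruments, canonicalises the alter labels, and collapses duplicate
#' nominations of the same category to a single placement at the innermost
#' (most influential) circle. An ego with zero placements is rejected — the
#' study excluded non-completers, and a completer by definition nominated at
#' least one alter.
#'
#' @param id Participant identifier.
#' @param severity_response Canonical response to the severity question
#'   (see [severity_responses()]).
#' @param rqlq Either a numeric vector of mini-RQLQ item scores or a single
#'   precomputed mean score (`rqlq_is_mean = TRUE`).
#' @param alters Character vector of alter labels (raw or canonical).
#' @param circles Integer vector of circle placements, one per alter, each in
#'   `1:n_circles` (1 = most influential).
#' @param age,sex,region Optional demographics.
#' @param taxonomy An [alter_taxonomy()].
#' @param qol_breaks Passed to [bin_qol()].
#' @param rqlq_is_mean Set `TRUE` when `rqlq` is a precomputed mean score.
#' @param n_circles Number of concentric circles (default 4).
#' @return An object of class `ar_participant`.
#' @export
#' @examples
#' build_ego_network("p1", "Never", rqlq = rep(0, 14),
#'                   alters = c("GP", "internet"), circles = c(1, 3))
build_ego_network <- function(id, severity_response, rqlq, alters, circles,
                              age = NA, sex = NA, region = NA,
                              taxonomy = alter_taxonomy(),
                              qol_breaks = c(2, 4),
                              rqlq_is_mean = FALSE, n_circles = 4) {
  if (length(alters) == 0 || length(circles) == 0) {
    stop("participant ", id, ": at least one (alter, circle) placement ",
         "is required", call. = FALSE)
  }
  if (length(alters) != length(circles)) {
    stop("participant ", id, ": alters and circles differ in length",
         call. = FALSE)
  }
  circles <- as.integer(circles)
  if (anyNA(circles) || any(circles < 1 | circles > n_circles)) {
    stop("participant ", id, ": circles must be integers in 1..", n_circles,
         call. = FALSE)
  }
  if (isTRUE(rqlq_is_mean)) {
    stopifnot(is.numeric(rqlq), length(rqlq) == 1)
    if (is.na(rqlq) || rqlq < 0 || rqlq > 6) {
      stop("participant ", id, ": mean mini-RQLQ score must be in [0, 6]",
           call. = FALSE)
    }
    rqlq <- structure(list(items = NULL, mean_score = as.numeric(rqlq)),
                      class = "mini_rqlq")
  } else {
    rqlq <- score_mini_rqlq(rqlq)
  }
  codes <- canonicalize_alter(as.character(alters), taxonomy)
  # innermost-wins collapse of duplicate categories: sort by circle, keep
  # each category's first (innermost) occurrence
  ord <- order(circles, codes)
  keep <- ord[!duplicated(codes[ord])]
  pl <- data.frame(alter = codes[keep], circle = circles[keep],
                   stringsAsFactors = FALSE)
  pl <- pl[order(pl$circle, pl$alter), , drop = FALSE]
  rownames(pl) <- NULL
  structure(
    list(
      id = as.character(id),
      age = age, sex = sex, region = region,
      severity = classify_severity(severity_response),
      rqlq = rqlq,
      qol = bin_qol(rqlq$mean_score, breaks = qol_breaks),
      placements = pl
    ),
    class = "ar_participant"
  )
}

#' @export
print.ar_participant <- function(x, ...) {
  cat("<ar_participant>", x$id, "| severity:", x$severity,
      "| QOL:", x$qol,
      "| mini-RQLQ mean:", format(x$rqlq$mean_score, digits = 3),
      "|", nrow(x$placements), "alter(s)\n")
  invisible(x)
}

#' Coerce to an ego cohort
#'
#' An `ar_cohort` is an ordered list of `ar_participant` objects; the order is
#' interview order, which matters for saturation detection.
#'
#' @param x A list of `ar_participant` objects or an existing `ar_cohort` /
#'   `ar_cohort_network`.
#' @return An `ar_cohort`.
#' @export
as_ar_cohort <- function(x) {
  if (inherits(x, "ar_cohort_network")) x <- x$egos
  if (inherits(x, "ar_participant")) x <- list(x)
  ok <- vapply(x, inherits, logical(1), what = "ar_participant")
  if (!all(ok)) stop("all elements must be ar_participant objects",
                     call. = FALSE)
  structure(x, class = "ar_cohort")
}

#' Aggregate ego networks into a cohort network
#'
#' Tabulates, for each alter category, the number of participants who placed
#' it on each circle (`n1..n4`). Each ego contributes at most one count per
#' category (duplicates were collapsed at build time), so for every alter
#' `n1 + ... + n4` equals the number of distinct egos nominating it.
#'
#' @param egos A list of `ar_participant` objects (or an `ar_cohort`).
#' @param n_circles Number of circles (default 4).
#' @return Object of class `ar_cohort_network`: list with `egos` (the
#'   `ar_cohort`) and `counts` (data.frame `alter`, `n1`..`n4`, alphabetical
#'   by alter code).
#' @export
aggregate_cohort <- function(egos, n_circles = 4) {
  cohort <- as_ar_cohort(egos)
  if (length(cohort) == 0) stop("cohort must contain at least one participant",
                                call. = FALSE)
  ids <- vapply(cohort, function(p) p$id, character(1))
  if (anyDuplicated(ids)) {
    stop("duplicate participant id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  pl <- cohort_placements(cohort)
  alters <- sort(unique(pl$alter))
  counts <- vapply(seq_len(n_circles), function(cc) {
    vapply(alters, function(a) sum(pl$alter == a & pl$circle == cc),
           integer(1))
  }, integer(length(alters)))
  counts <- matrix(counts, nrow = length(alters),
                   dimnames = list(NULL, paste0("n", seq_len(n_circles))))
  structure(
    list(egos = cohort,
         counts = cbind(data.frame(alter = alters, stringsAsFactors = FALSE),
                        as.data.frame(counts)),
         n_circles = n_circles),
    class = "ar_cohort_network"
  )
}

#' Flatten a cohort to its (ego, alter, circle) placements
#'
#' @param cohort An `ar_cohort` or `ar_cohort_network`.
#' @return data.frame with columns `ego`, `alter`, `circle`.
#' @export
cohort_placements <- function(cohort) {
  cohort <- as_ar_cohort(cohort)
  if (length(cohort) == 0) {
    return(data.frame(ego = character(0), alter = character(0),
                      circle = integer(0), stringsAsFactors = FALSE))
  }
  ns <- vapply(cohort, function(p) nrow(p$placements), integer(1))
  ids <- vapply(cohort, function(p) p$id, character(1))
  data.frame(
    ego = rep(ids, ns),
    alter = unlist(lapply(cohort, function(p) p$placements$alter),
                   use.names = FALSE),
    circle = unlist(lapply(cohort, function(p) p$placements$circle),
                    use.names = FALSE),
    stringsAsFactors = FALSE
  )
}

#' @export
print.ar_cohort_network <- function(x, ...) {
  cat("<ar_cohort_network>", length(x$egos), "ego(s),",
      nrow(x$counts), "alter categorie(s),",
      sum(as.matrix(x$counts[, -1])), "placement(s)\n")
  invisible(x)
}

#' Restrict a cohort network to one QOL category
#'
#' Keeps exactly the egos whose mini-RQLQ mean fell in the given impairment
#' category and re-tabulates the placement counts from scratch. An empty
#' subgroup is a valid result (`NULL` egos, zero-row counts).
#'
#' @param cohort An `ar_cohort_network`.
#' @param category One of [qol_levels()].
#' @return An `ar_cohort_network` (possibly empty).
#' @export
filter_by_qol <- function(cohort, category) {
  stopifnot(inherits(cohort, "ar_cohort_network"))
  category <- match.arg(category, qol_levels())
  keep <- vapply(cohort$egos, function(p) p$qol == category, logical(1))
  egos <- cohort$egos[keep]
  if (length(egos) == 0) {
    return(structure(
      list(egos = structure(list(), class = "ar_cohort"),
           counts = cbind(data.frame(alter = character(0),
                                     stringsAsFactors = FALSE),
                          as.data.frame(matrix(integer(0), nrow = 0,
                            ncol = cohort$n_circles,
                            dimnames = list(NULL,
                              paste0("n", seq_len(cohort$n_circles)))))),
           n_circles = cohort$n_circles),
      class = "ar_cohort_network"
    ))
  }
  aggregate_cohort(egos, n_circles = cohort$n_circles)
}
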