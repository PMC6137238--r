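#' Round a percentage half-away-from-zero
#'
#' The shared rounding rule for every printed percentage in the analysis.
#' Unlike base [round()] (banker's rounding), exact halves round away from
#' zero, which reproduces the conventional hand-rounded values in study
#' reports (e.g. 20/41 -> 48.8, 41/47 -> 87 at 0 dp).
#'
#' @param count Numerator count(s), `0 <= count <= total`.
#' @param total Positive denominator.
#' @param decimals Decimal places to keep (default 1).
#' @return Numeric vector of rounded percentages.
#' @export
#' @examples
#' percentage(20, 41)       # 48.8
#' percentage(41, 47, 0)    # 87
percentage <- function(count, total, decimals = 1) {
  stopifnot(is.numeric(count), is.numeric(total), length(total) == 1)
  if (is.na(total) || total <= 0) {
    stop("total must be a positive number", call. = FALSE)
  }
  if (anyNA(count) || any(count < 0) || any(count > total)) {
    stop("count must satisfy 0 <= count <= total", call. = FALSE)
  }
  p <- 100 * count / total
  f <- 10^decimals
  # 1e-9 guards against p*f landing a hair under an exact half
  sign(p) * floor(abs(p) * f + 0.5 + 1e-9) / f
}

#' Weighted alter score
#'
#' The study's influence score for one alter category:
#' `score = 4*n1 + 3*n2 + 2*n3 + 1*n4`, where `n_k` is the number of
#' participants who placed the alter on circle k. Circle One (innermost, most
#' influential) carries the largest weight. Weights are configurable; the
#' default generalises to c circles as `c, c-1, ..., 1`.
#'
#' @param n1,n2,n3,n4 Non-negative integer counts per circle (vectorised).
#' @param weights Circle weights, innermost first (default `c(4, 3, 2, 1)`).
#' @return Numeric vector of scores.
#' @export
#' @examples
#' alter_score(2, 1, 0, 3)  # 14
alter_score <- function(n1, n2, n3, n4, weights = c(4, 3, 2, 1)) {
  counts <- cbind(n1, n2, n3, n4)
  if (anyNA(counts) || any(counts < 0) || any(counts != trunc(counts))) {
    stop("circle counts must be non-negative integers", call. = FALSE)
  }
  stopifnot(length(weights) == ncol(counts), all(weights >= 0))
  as.numeric(counts %*% weights)
}

#' Network alter density table
#'
#' For each alter category in a (sub)network, the weighted alter score and the
#' network alter density: the score as a percentage of the sum of all alter
#' scores. Densities sum to 100; a larger density means a stronger influence
#' within the network. Rows are sorted by descending density with alphabetical
#' tie-break so output is deterministic.
#'
#' @param cohort An `ar_cohort_network` with at least one placement.
#' @param weights Circle weights, innermost first; defaults to the number of
#'   circles counting down to 1.
#' @return data.frame `alter`, `n1`..`n4`, `score`, `density` (unrounded).
#' @export
network_alter_density <- function(cohort, weights = NULL) {
  stopifnot(inherits(cohort, "ar_cohort_network"))
  counts <- cohort$counts
  if (nrow(counts) == 0 || sum(as.matrix(counts[, -1])) == 0) {
    stop("cohort has no placements", call. = FALSE)
  }
  if (is.null(weights)) weights <- seq(cohort$n_circles, 1)
  stopifnot(length(weights) == cohort$n_circles)
  score <- as.numeric(as.matrix(counts[, -1]) %*% weights)
  out <- cbind(counts, score = score,
               density = 100 * score / sum(score))
  out <- out[order(-out$density, out$alter), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-alter composition of one circle
#'
#' For the given circle, counts the participants who placed each alter there
#' and reports two percentages: `pct_of_cohort` (denominator = number of egos,
#' the denominator consistent with the study's Circle-One figures) and
#' `pct_of_circle` (denominator = all placements on that circle).
#'
#' @param cohort An `ar_cohort_network`.
#' @param circle Circle number in `1:n_circles`.
#' @param decimals Decimal places for the percentages (default 0, as printed).
#' @return data.frame `alter`, `count`, `pct_of_cohort`, `pct_of_circle`,
#'   sorted by descending count then alphabetically; zero-count alters are
#'   dropped (an empty circle gives a zero-row table).
#' @export
circle_composition <- function(cohort, circle, decimals = 0) {
  stopifnot(inherits(cohort, "ar_cohort_network"))
  if (!is.numeric(circle) || length(circle) != 1 ||
      !(circle %in% seq_len(cohort$n_circles))) {
    stop("circle must be one of 1..", cohort$n_circles, call. = FALSE)
  }
  cnt <- cohort$counts[[paste0("n", circle)]]
  keep <- which(cnt > 0)
  if (length(keep) == 0) {
    return(data.frame(alter = character(0), count = integer(0),
                      pct_of_cohort = numeric(0), pct_of_circle = numeric(0),
                      stringsAsFactors = FALSE))
  }
  out <- data.frame(
    alter = cohort$counts$alter[keep],
    count = as.integer(cnt[keep]),
    pct_of_cohort = percentage(cnt[keep], length(cohort$egos), decimals),
    pct_of_circle = percentage(cnt[keep], sum(cnt), decimals),
    stringsAsFactors = FALSE
  )
  out <- out[order(-out$count, out$alter), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Network-size summary
#'
#' Per-ego alter counts with minimum, maximum, mean, median and mode(s). All
#' modes are reported when the distribution is multimodal; the study itself
#' prints "an average number of 4" alongside both "a median of 5" and
#' "a mode of 5" in different sections, so no single summary is privileged.
#'
#' @param cohort An `ar_cohort` or `ar_cohort_network`.
#' @return List of class `network_size_summary`: `counts`, `min`, `max`,
#'   `mean`, `median`, `modes`.
#' @export
network_size_summary <- function(cohort) {
  cohort <- as_ar_cohort(cohort)
  if (length(cohort) == 0) stop("cohort must contain at least one participant",
                                call. = FALSE)
  counts <- vapply(cohort, function(p) nrow(p$placements), integer(1))
  tab <- table(counts)
  modes <- as.integer(names(tab)[tab == max(tab)])
  structure(
    list(counts = counts, min = min(counts), max = max(counts),
         mean = mean(counts), median = stats::median(counts), modes = modes),
    class = "network_size_summary"
  )
}

#' @export
print.network_size_summary <- function(x, ...) {
  cat("network size: min", x$min, "max", x$max,
      "mean", format(x$mean, digits = 3), "median", x$median,
      "mode(s)", paste(x$modes, collapse = ", "), "\n")
  invisible(x)
}
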