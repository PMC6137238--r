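#' Canonical AR severity response table
#'
#' The five canonical responses to the single screening question
#' "Do you have any of the following symptoms: itchy, runny, blocked nose or
#' sneezing when you do not have a cold?" and the ARIA-style severity category
#' each maps to (intermittent vs persistent crossed with mild vs
#' moderate-to-severe, plus "none").
#'
#' @return A data.frame with columns `response` (canonical response string),
#'   `code` (machine category code) and `label` (display label).
#' @export
#' @examples
#' severity_responses()
severity_responses <- function() {
  data.frame(
    response = c(
      "Never",
      "Occasionally and are of little bother",
      "Occasionally and are quite a bother",
      "Most days but are of little bother",
      "Most days and are a lot of bother"
    ),
    code = severity_levels(),
    label = c(
      "None",
      "Mild intermittent",
      "Moderate to severe intermittent",
      "Mild persistent",
      "Moderate to severe persistent"
    ),
    stringsAsFactors = FALSE
  )
}

#' @rdname severity_responses
#' @export
severity_levels <- function() {
  c("none", "mild_intermittent", "moderate_severe_intermittent",
    "mild_persistent", "moderate_severe_persistent")
}

#' Ordered quality-of-life impairment levels
#'
#' @return Character vector of the four QOL category codes, least to most
#'   impaired.
#' @export
qol_levels <- function() {
  c("QOL_ZERO", "QOL_MILD", "QOL_MOD", "QOL_SEV")
}

# collapse whitespace, trim, case-fold -- shared by severity and alter matching
normalize_label <- function(x) {
  x <- tolower(trimws(x))
  gsub("\\s+", " ", x)
}

#' Classify the AR severity screening response
#'
#' Matches a response string against the five canonical responses
#' (case-insensitive, whitespace-normalised, otherwise exact: no fuzzy
#' matching, so misspelled responses are rejected rather than silently
#' misclassified).
#'
#' @param response Character vector of response strings.
#' @return Character vector of severity category codes (see
#'   [severity_levels()]).
#' @export
#' @examples
#' classify_severity("Never")
#' classify_severity("most days and are a lot of bother")
classify_severity <- function(response) {
  stopifnot(is.character(response), length(response) >= 1)
  tab <- severity_responses()
  idx <- match(normalize_label(response), normalize_label(tab$response))
  if (anyNA(idx)) {
    bad <- unique(response[is.na(idx)])
    stop("unknown severity response(s): ", paste(sQuote(bad), collapse = ", "),
         "; canonical responses are: ",
         paste(sQuote(tab$response), collapse = ", "), call. = FALSE)
  }
  tab$code[idx]
}

#' Score the mini-RQLQ questionnaire
#'
#' The mini Rhinoconjunctivitis Quality of Life Questionnaire has items scored
#' 0 (not troubled) to 6 (extremely troubled) and is summarised by the
#' unweighted arithmetic mean of the item scores.
#'
#' @param item_scores Numeric vector of item scores, each in \[0, 6\].
#' @return An object of class `mini_rqlq`: list with `items` and `mean_score`.
#' @export
#' @examples
#' score_mini_rqlq(c(1, 2, 3, 4))$mean_score  # 2.5
score_mini_rqlq <- function(item_scores) {
  if (length(item_scores) == 0) {
    stop("item_scores must be a non-empty numeric vector", call. = FALSE)
  }
  if (!is.numeric(item_scores) || anyNA(item_scores) ||
      any(item_scores < 0 | item_scores > 6)) {
    stop("mini-RQLQ item scores must be numbers in [0, 6]", call. = FALSE)
  }
  structure(
    list(items = as.numeric(item_scores), mean_score = mean(item_scores)),
    class = "mini_rqlq"
  )
}

#' Bin a mini-RQLQ mean score into a QOL impairment category
#'
#' The study's printed bins ("score zero", ">0-2", "3-4", "5-6") leave the
#' intervals (2,3) and (4,5) unmapped although mean scores are continuous.
#' The default here is the continuous half-open partition ZERO = \{0\},
#' MILD = (0, 2\], MOD = (2, 4\], SEV = (4, 6\], which preserves every printed
#' upper bound. The two interior breaks are configurable.
#'
#' @param mean_score Numeric vector of mean scores in \[0, 6\].
#' @param breaks Upper bounds of the MILD and MOD bins (default `c(2, 4)`).
#' @return Character vector of QOL codes (see [qol_levels()]).
#' @export
#' @examples
#' bin_qol(c(0, 2, 2.6, 5))
bin_qol <- function(mean_score, breaks = c(2, 4)) {
  stopifnot(is.numeric(mean_score), length(mean_score) >= 1,
            length(breaks) == 2, breaks[1] > 0, breaks[2] > breaks[1],
            breaks[2] < 6)
  if (anyNA(mean_score) || any(mean_score < 0 | mean_score > 6)) {
    stop("mean_score must be in [0, 6]", call. = FALSE)
  }
  lv <- qol_levels()
  out <- character(length(mean_score))
  out[mean_score == 0] <- lv[1]
  out[mean_score > 0 & mean_score <= breaks[1]] <- lv[2]
  out[mean_score > breaks[1] & mean_score <= breaks[2]] <- lv[3]
  out[mean_score > breaks[2]] <- lv[4]
  out
}

#' Tabulate the severity distribution of a cohort
#'
#' @param cohort An `ar_cohort` (list of participants, see
#'   [build_ego_network()]).
#' @param decimals Decimal places for the percentage column (default 1, as
#'   printed in the study's Table 1).
#' @return data.frame with one row per severity category (all five always
#'   present, zero rows included): `code`, `label`, `count`, `pct`.
#' @export
severity_distribution <- function(cohort, decimals = 1) {
  cohort <- as_ar_cohort(cohort)
  if (length(cohort) == 0) stop("cohort must contain at least one participant",
                                call. = FALSE)
  sev <- vapply(cohort, function(p) p$severity, character(1))
  tab <- severity_responses()
  counts <- vapply(tab$code, function(cd) sum(sev == cd), integer(1))
  data.frame(
    code = tab$code,
    label = tab$label,
    count = as.integer(counts),
    pct = percentage(counts, length(cohort), decimals),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}

#' Tabulate the QOL-category distribution of a cohort
#'
#' @inheritParams severity_distribution
#' @return data.frame with columns `code`, `count`, `pct`, one row per QOL
#'   category in order ZERO, MILD, MOD, SEV.
#' @export
qol_distribution <- function(cohort, decimals = 1) {
  cohort <- as_ar_cohort(cohort)
  if (length(cohort) == 0) stop("cohort must contain at least one participant",
                                call. = FALSE)
  q <- vapply(cohort, function(p) p$qol, character(1))
  counts <- vapply(qol_levels(), function(cd) sum(q == cd), integer(1))
  data.frame(
    code = qol_levels(),
    count = as.integer(counts),
    pct = percentage(counts, length(cohort), decimals),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}
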