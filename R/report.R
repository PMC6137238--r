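#' Build the full analysis report for a cohort
#'
#' Reproduces the study's reporting surface from a cohort: the severity
#' distribution (Table-1 shape), the QOL-category distribution, the
#' network-size summary, the saturation index and per-participant log, the
#' total density table, one density table per QOL subgroup, and the Circle-One
#' composition. All percentages use the shared half-away-from-zero
#' [percentage()] rule; all tables have deterministic row order.
#'
#' @param cohort An `ar_cohort` or `ar_cohort_network` (interview order
#'   preserved).
#' @param weights Circle weights for the density tables (default
#'   `n_circles..1`).
#' @param seed Optional seed recorded in the report header (provenance only;
#'   the report itself is deterministic).
#' @return Object of class `ar_report`.
#' @export
build_report <- function(cohort, weights = NULL, seed = NA) {
  if (!inherits(cohort, "ar_cohort_network")) {
    cohort <- aggregate_cohort(cohort)
  }
  egos <- cohort$egos
  sat <- saturation_index(egos)
  by_qol <- lapply(qol_levels(), function(q) {
    sub <- filter_by_qol(cohort, q)
    if (length(sub$egos) == 0) return(NULL)
    network_alter_density(sub, weights = weights)
  })
  names(by_qol) <- qol_levels()
  structure(
    list(
      n = length(egos),
      seed = seed,
      severity = severity_distribution(egos),
      qol = qol_distribution(egos),
      network_size = network_size_summary(egos),
      saturation = sat,
      density_total = network_alter_density(cohort, weights = weights),
      density_by_qol = by_qol,
      circle_one = circle_composition(cohort, 1)
    ),
    class = "ar_report"
  )
}

#' @export
print.ar_report <- function(x, digits = 1, ...) {
  cat("AR influence-network report (n =", x$n, "egos)\n")
  cat("\n-- AR severity --\n")
  print(x$severity, row.names = FALSE)
  cat("\n-- QOL impairment (mini-RQLQ) --\n")
  print(x$qol, row.names = FALSE)
  cat("\n-- Network size --\n")
  print(x$network_size)
  cat("\n-- Saturation --\nlast new alter introduced by participant",
      x$saturation$index, "of", x$n, "\n")
  cat("\n-- Network alter density (total) --\n")
  dt <- x$density_total
  dt$density <- round(dt$density, digits)
  print(dt, row.names = FALSE)
  for (q in names(x$density_by_qol)) {
    d <- x$density_by_qol[[q]]
    if (is.null(d)) next
    cat("\n-- Network alter density (", q, ") --\n", sep = "")
    d$density <- round(d$density, digits)
    print(d, row.names = FALSE)
  }
  cat("\n-- Circle One composition --\n")
  print(x$circle_one, row.names = FALSE)
  invisible(x)
}

#' Write a report as machine-readable JSON
#'
#' @param report An `ar_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  stopifnot(inherits(report, "ar_report"))
  x <- unclass(report)
  x$network_size <- unclass(x$network_size)
  x$saturation$log <- lapply(x$saturation$log, as.character)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(path)
}

#' HCP share of network influence
#'
#' Sums the density of every alter whose taxonomy group is `HCP`, giving the
#' share of total influence attributed to health-care professionals — the
#' quantity the study tracks across QOL subgroups.
#'
#' @param density A density table from [network_alter_density()].
#' @param taxonomy An [alter_taxonomy()].
#' @return A single number in \[0, 100\].
#' @export
hcp_density_share <- function(density, taxonomy = alter_taxonomy()) {
  grp <- taxonomy$group[match(density$alter, taxonomy$code)]
  sum(density$density[!is.na(grp) & grp == "HCP"])
}
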