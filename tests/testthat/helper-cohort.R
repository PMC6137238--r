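# shared fixtures: all cohorts are built in code, none stored on disk

TAX <- alter_taxonomy()

make_ego <- function(id, alters, circles,
                     sev = "Never", rqlq_mean = 1, rqlq_items = NULL) {
  build_ego_network(
    id = id, severity_response = sev,
    rqlq = if (is.null(rqlq_items)) rqlq_mean else rqlq_items,
    rqlq_is_mean = is.null(rqlq_items),
    alters = alters, circles = circles, taxonomy = TAX
  )
}

# small random cohort; caller controls the RNG state
random_cohort <- function(n_egos = 5) {
  egos <- lapply(seq_len(n_egos), function(i) {
    k <- sample(1:6, 1)
    make_ego(sprintf("e%02d", i),
             alters = sample(TAX$code, k),
             circles = sample(1:4, k, replace = TRUE),
             sev = sample(severity_responses()$response, 1),
             rqlq_mean = stats::runif(1, 0, 6))
  })
  as_ar_cohort(egos)
}

random_cohort_fixed <- function() {
  set.seed(99)
  random_cohort(3)
}

# independent density oracle: unweighted loop over individual placements,
# no reference to the closed-form counts path
oracle_density <- function(placements, weights = c(4, 3, 2, 1)) {
  scores <- list()
  for (i in seq_len(nrow(placements))) {
    a <- placements$alter[i]
    w <- weights[placements$circle[i]]
    scores[[a]] <- (if (is.null(scores[[a]])) 0 else scores[[a]]) + w
  }
  s <- unlist(scores)
  d <- 100 * s / sum(s)
  d[order(-d, names(d))]
}

# 41-ego interview ordering whose last first-appearance alter is at ego 20
saturating_cohort <- function() {
  cats <- TAX$code
  egos <- vector("list", 41)
  for (i in 1:13) {
    alters <- unique(c(cats[i], cats[1]))
    egos[[i]] <- make_ego(paste0("s", i), alters,
                          circles = seq_along(alters))
  }
  for (i in 14:19) egos[[i]] <- make_ego(paste0("s", i), cats[1], 1)
  egos[[20]] <- make_ego("s20", c(cats[14], cats[1]), c(1, 2))
  for (i in 21:41) egos[[i]] <- make_ego(paste0("s", i),
                                         c(cats[1], cats[2]), c(1, 2))
  as_ar_cohort(egos)
}
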