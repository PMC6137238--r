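test_that("build_ego_network validates, canonicalises and collapses", {
  one <- make_ego("p1", "GP", 1)
  expect_s3_class(one, "ar_participant")
  expect_equal(nrow(one$placements), 1)
  expect_identical(one$placements$alter, "gp")
  # duplicate category collapses to the innermost circle
  dup <- make_ego("p2", c("GP", "gp"), c(3, 1))
  expect_equal(dup$placements,
               data.frame(alter = "gp", circle = 1L, stringsAsFactors = FALSE))
  # more placements than the observed study maximum is fine
  twelve <- make_ego("p3", TAX$code[1:12], rep(1:4, 3))
  expect_equal(nrow(twelve$placements), 12)
  expect_error(make_ego("p4", character(0), integer(0)), "at least one")
  expect_error(make_ego("p5", "GP", 5), "circles must be")
  expect_error(make_ego("p6", "GP", 0), "circles must be")
})

test_that("instrument fields are scored at build time", {
  ego <- build_ego_network("p1", "Most days and are a lot of bother",
                           rqlq = c(3, 3, 4, 2), alters = "GP", circles = 1)
  expect_identical(ego$severity, "moderate_severe_persistent")
  expect_equal(ego$rqlq$mean_score, 3)
  expect_identical(ego$qol, "QOL_MOD")
  # precomputed mean accepted when items are absent
  ego2 <- make_ego("p2", "GP", 1, rqlq_mean = 0)
  expect_identical(ego2$qol, "QOL_ZERO")
  expect_null(ego2$rqlq$items)
})

test_that("aggregate_cohort tabulates per-circle participant counts", {
  two <- as_ar_cohort(list(make_ego("a", "GP", 1), make_ego("b", "GP", 1)))
  net <- aggregate_cohort(two)
  expect_equal(net$counts$n1[net$counts$alter == "gp"], 2L)
  expect_equal(sum(as.matrix(net$counts[, -1])), 2)
  one <- aggregate_cohort(list(make_ego("a", c("GP", "media"), c(1, 4))))
  cc <- one$counts
  expect_equal(unlist(cc[cc$alter == "gp", -1], use.names = FALSE),
               c(1L, 0L, 0L, 0L))
  expect_equal(unlist(cc[cc$alter == "media", -1], use.names = FALSE),
               c(0L, 0L, 0L, 1L))
  expect_error(aggregate_cohort(list()), "at least one")
  expect_error(
    aggregate_cohort(list(make_ego("a", "GP", 1), make_ego("a", "media", 2))),
    "duplicate participant"
  )
})

test_that("for each alter n1..n4 sums to the number of nominating egos", {
  set.seed(7)
  for (rep in 1:20) {
    cohort <- random_cohort(8)
    net <- aggregate_cohort(cohort)
    pl <- cohort_placements(cohort)
    per_alter <- rowSums(net$counts[, -1])
    expected <- vapply(net$counts$alter,
                       function(a) length(unique(pl$ego[pl$alter == a])),
                       integer(1))
    expect_equal(unname(per_alter), unname(as.numeric(expected)))
    expect_equal(sum(per_alter), nrow(pl))
  }
})

test_that("QOL filtering partitions the cohort and preserves counts", {
  set.seed(31)
  for (rep in 1:10) {
    net <- aggregate_cohort(random_cohort(12))
    subs <- lapply(qol_levels(), function(q) filter_by_qol(net, q))
    ids <- lapply(subs, function(s) vapply(s$egos, function(p) p$id,
                                           character(1)))
    # disjoint and exhaustive
    expect_equal(sum(lengths(ids)), length(net$egos))
    expect_setequal(unlist(ids),
                    vapply(net$egos, function(p) p$id, character(1)))
    # aggregation consistency: subgroup counts sum to total counts
    total <- net$counts
    for (a in total$alter) {
      sub_sum <- sum(vapply(subs, function(s) {
        if (nrow(s$counts) == 0) return(0)
        r <- s$counts[s$counts$alter == a, -1]
        if (nrow(r) == 0) 0 else sum(r)
      }, numeric(1)))
      expect_equal(sub_sum, sum(total[total$alter == a, -1]))
    }
  }
  # empty subgroup is valid
  net1 <- aggregate_cohort(list(make_ego("a", "GP", 1, rqlq_mean = 0)))
  empty <- filter_by_qol(net1, "QOL_SEV")
  expect_length(empty$egos, 0)
  expect_equal(nrow(empty$counts), 0)
})

test_that("flattening an ego reproduces its collapsed placements", {
  set.seed(13)
  for (rep in 1:20) {
    k <- sample(1:8, 1)
    raw_alters <- sample(TAX$code, k, replace = TRUE)
    raw_circles <- sample(1:4, k, replace = TRUE)
    ego <- make_ego("rt", raw_alters, raw_circles)
    # oracle collapse: min circle per category
    expected <- tapply(raw_circles, raw_alters, min)
    got <- stats::setNames(ego$placements$circle, ego$placements$alter)
    expect_setequal(names(got), names(expected))
    expect_equal(as.integer(got[sort(names(got))]),
                 as.integer(expected[sort(names(got))]))
  }
})
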