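test_that("alter_score evaluates the weighted count formula", {
  expect_equal(alter_score(1, 0, 0, 0), 4)
  expect_equal(alter_score(0, 0, 0, 1), 1)
  expect_equal(alter_score(2, 1, 0, 3), 14)  # 8 + 3 + 0 + 3
  expect_equal(alter_score(c(1, 0), c(0, 0), c(0, 0), c(0, 1)), c(4, 1))
  expect_equal(alter_score(1, 1, 1, 1, weights = c(10, 0, 0, 0)), 10)
  expect_error(alter_score(-1, 0, 0, 0), "non-negative")
  expect_error(alter_score(1.5, 0, 0, 0), "integer")
})

test_that("network_alter_density normalises, sorts and matches examples", {
  # single alter anywhere -> 100
  solo <- aggregate_cohort(list(make_ego("a", "media", 3)))
  expect_equal(network_alter_density(solo)$density, 100)
  # A@1 vs B@4 -> 80 / 20
  ab <- aggregate_cohort(list(make_ego("a", c("GP", "media"), c(1, 4))))
  d <- network_alter_density(ab)
  expect_equal(d$alter, c("gp", "media"))
  expect_equal(d$density, c(80, 20))
  # scores (14, 4, 2) -> densities (70, 20, 10); constructed placements
  cohort <- as_ar_cohort(list(
    make_ego("e1", c("GP", "pharmacist"), c(1, 1)),
    make_ego("e2", c("GP", "media"), c(1, 3)),
    make_ego("e3", c("GP", "GP"), c(2, 4)),   # collapses to circle 2
    make_ego("e4", c("GP", "GP"), c(4, 2))    # same, order reversed
  ))
  net <- aggregate_cohort(cohort)
  d <- network_alter_density(net)
  expect_equal(d$score[d$alter == "gp"], 4 + 4 + 3 + 3)    # 14
  expect_equal(d$density, sort(100 * d$score / sum(d$score),
                               decreasing = TRUE))
  expect_error(network_alter_density(
    structure(list(egos = list(), n_circles = 4,
                   counts = data.frame(alter = character(0))),
              class = "ar_cohort_network")), "no placements")
})

test_that("closed-form densities match the brute-force placement oracle", {
  set.seed(211)
  for (rep in 1:200) {
    cohort <- random_cohort(sample(2:8, 1))
    net <- aggregate_cohort(cohort)
    d <- network_alter_density(net)
    got <- stats::setNames(d$density, d$alter)
    want <- oracle_density(cohort_placements(cohort))
    expect_equal(got, want, tolerance = 1e-12)
    expect_lt(abs(sum(d$density) - 100), 1e-9)
  }
})

test_that("moving a placement inward raises that alter and lowers the rest", {
  set.seed(97)
  for (rep in 1:30) {
    cohort <- random_cohort(6)
    net <- aggregate_cohort(cohort)
    d0 <- network_alter_density(net)
    # pick a movable placement (circle > 1)
    pl <- cohort_placements(cohort)
    mv <- which(pl$circle > 1)
    if (!length(mv)) next
    i <- sample(mv, 1)
    egos <- unclass(as_ar_cohort(cohort))
    j <- which(vapply(egos, function(p) p$id, character(1)) == pl$ego[i])
    k <- which(egos[[j]]$placements$alter == pl$alter[i])
    egos[[j]]$placements$circle[k] <- egos[[j]]$placements$circle[k] - 1L
    d1 <- network_alter_density(aggregate_cohort(as_ar_cohort(egos)))
    a <- pl$alter[i]
    expect_gt(d1$density[d1$alter == a], d0$density[d0$alter == a])
    others <- setdiff(d0$alter, a)
    expect_true(all(d1$density[match(others, d1$alter)] <
                      d0$density[match(others, d0$alter)]))
  }
})

test_that("densities are invariant to scaling all circle counts", {
  set.seed(53)
  for (rep in 1:20) {
    net <- aggregate_cohort(random_cohort(6))
    d0 <- network_alter_density(net)
    k <- sample(2:7, 1)
    scaled <- net
    scaled$counts[, -1] <- scaled$counts[, -1] * k
    d1 <- network_alter_density(scaled)
    expect_equal(d1$density, d0$density, tolerance = 1e-12)
  }
})

test_that("circle_composition reports both denominators", {
  cohort <- as_ar_cohort(list(
    make_ego("a", c("GP", "media"), c(1, 1)),
    make_ego("b", "GP", 1),
    make_ego("c", "pharmacist", 2)
  ))
  net <- aggregate_cohort(cohort)
  c1 <- circle_composition(net, 1)
  expect_equal(c1$count[c1$alter == "gp"], 2L)
  expect_equal(c1$pct_of_cohort[c1$alter == "gp"], percentage(2, 3, 0))
  expect_equal(c1$pct_of_circle[c1$alter == "gp"], percentage(2, 3, 0))
  # one alter alone on a circle -> 100% of that circle's placements
  c2 <- circle_composition(net, 2)
  expect_equal(c2$pct_of_circle, 100)
  # empty circle -> zero-row table
  expect_equal(nrow(circle_composition(net, 4)), 0)
  expect_error(circle_composition(net, 5), "circle must be")
})

test_that("network_size_summary reports all five summaries and multimodes", {
  mk <- function(sizes) as_ar_cohort(lapply(seq_along(sizes), function(i) {
    make_ego(paste0("p", i), TAX$code[seq_len(sizes[i])],
             rep(1:4, length.out = sizes[i]))
  }))
  s <- network_size_summary(mk(c(1, 11)))
  expect_equal(c(s$min, s$max, s$mean), c(1, 11, 6))
  s2 <- network_size_summary(mk(c(5, 5, 3)))
  expect_equal(s2$modes, 5L)
  expect_equal(s2$median, 5)
  s3 <- network_size_summary(mk(c(2, 2, 3, 3)))
  expect_equal(s3$modes, c(2L, 3L))
})

test_that("percentage rounds half away from zero at any precision", {
  expect_equal(percentage(20, 41, 1), 48.8)
  expect_equal(percentage(41, 47, 0), 87)
  expect_equal(percentage(0, 41, 1), 0)
  expect_equal(percentage(15, 41, 0), 37)
  expect_equal(percentage(1, 8, 0), 13)    # 12.5 rounds up, not to even
  expect_equal(percentage(1, 8, 1), 12.5)
  expect_equal(percentage(c(1, 3), 8, 1), c(12.5, 37.5))
  expect_error(percentage(1, 0), "positive")
  expect_error(percentage(5, 4), "count")
  expect_error(percentage(-1, 4), "count")
})
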