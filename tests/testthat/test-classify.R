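test_that("identical groups are not responsive and strong responses are", {
  expect_false(as.logical(classify_responsive(rep(5, 10), rep(5, 10), rep(5, 10))))
  expect_true(attr(classify_responsive(rep(5, 10), rep(5, 10), rep(5, 10)),
                   "flagged"))
  expect_error(classify_responsive(1:4, 1:10, 1:10), "at least 5")
})

test_that("a 3x-baseline response is detected with probability > 0.99", {
  set.seed(10)
  hits <- replicate(200, {
    base <- rpois(30, 10 * 1.5) / 1.5
    stim_a <- rpois(30, 30 * 0.3) / 0.3
    stim_b <- rpois(30, 10 * 0.3) / 0.3
    as.logical(classify_responsive(base, stim_a, stim_b))
  })
  expect_gt(mean(hits), 0.99)
})

test_that("null units are called responsive at roughly the nominal rate", {
  set.seed(11)
  fp <- replicate(2000, {
    as.logical(classify_responsive(rnorm(10, 10), rnorm(10, 10), rnorm(10, 10)))
  })
  # two Tukey-adjusted contrasts of three: familywise-controlled, so a bit
  # below alpha but the same order
  expect_gt(mean(fp), 0.01)
  expect_lt(mean(fp), 0.07)
})

test_that("preference follows the sign of the mean response-window bias", {
  expect_identical(classify_preference(c(0.4, -0.2, 0, NA)),
                   c("positive", "negative", "none", "none"))
})

test_that("touch effect detects constructed suppression and respects the null", {
  expect_identical(as.character(classify_touch_effect(rep(4, 10), rep(4, 10))),
                   "neither")
  set.seed(12)
  calls <- replicate(200, {
    base <- rpois(40, 10 * 1.5) / 1.5
    resp <- rpois(40, 5 * 0.3) / 0.3  # 50% suppression
    as.character(classify_touch_effect(resp, base))
  })
  expect_gt(mean(calls == "suppressed"), 0.95)
  fp <- replicate(1000, {
    x <- rnorm(20, 10); y <- rnorm(20, 10)
    as.character(classify_touch_effect(x, y)) != "neither"
  })
  expect_gt(mean(fp), 0.02)
  expect_lt(mean(fp), 0.08)
})

test_that("disengaged CR filtering follows the consecutive-miss rule", {
  # no miss runs: output equals input
  tr <- make_trials(c("Hit", "CR", "Hit", "CR"))
  expect_identical(filter_disengaged_cr(tr), tr)
  # H M M M M M CR CR H: the no-lick run holds 5 misses, both CRs removed
  tr <- make_trials(c("Hit", "Miss", "Miss", "Miss", "Miss", "Miss",
                      "CR", "CR", "Hit"))
  kept <- filter_disengaged_cr(tr)
  expect_identical(kept$outcome,
                   c("Hit", "Miss", "Miss", "Miss", "Miss", "Miss", "Hit"))
  # H M M CR M M H: only 4 misses in the run, CR retained
  tr <- make_trials(c("Hit", "Miss", "Miss", "CR", "Miss", "Miss", "Hit"))
  kept <- filter_disengaged_cr(tr)
  expect_identical(kept$outcome, tr$outcome)
  # CRs inside the run count as members but not toward the five misses
  tr <- make_trials(c("Miss", "CR", "Miss", "CR", "Miss", "Miss", "Miss", "Hit"))
  kept <- filter_disengaged_cr(tr)
  expect_identical(kept$outcome, c("Miss", "Miss", "Miss", "Miss", "Miss", "Hit"))
})

test_that("CR filtering never removes licked trials and keeps order", {
  set.seed(13)
  for (rep in 1:20) {
    tr <- make_trials(sample(c("Hit", "Miss", "CR", "FA"), 40, replace = TRUE))
    kept <- filter_disengaged_cr(tr)
    expect_true(all(tr$trial_id[tr$outcome %in% c("Hit", "FA")] %in%
                      kept$trial_id))
    expect_false(is.unsorted(kept$trial_id))
    expect_true(all(kept$trial_id %in% tr$trial_id))
  }
})

test_that("population preference statistics reproduce textbook chi-squared values", {
  # 50/50 split
  cl <- tibble::tibble(preference = rep(c("positive", "negative"), 100),
                       mouse_id = "m1")
  st <- population_preference_stats(cl)
  expect_equal(st$fraction_positive, 0.5)
  expect_equal(st$p_equal_split, 1)
  expect_true(st$single_mouse)
  # hand-built 2x2 table against the closed-form (Yates-corrected) value
  cl <- tibble::tibble(
    preference = c(rep("positive", 30), rep("negative", 10),
                   rep("positive", 20), rep("negative", 20)),
    mouse_id = rep(c("mA", "mB"), c(40, 40)))
  st <- population_preference_stats(cl)
  tab <- matrix(c(10, 30, 20, 20), 2, byrow = TRUE)
  n <- sum(tab); rs <- rowSums(tab); cs <- colSums(tab)
  expected <- outer(rs, cs) / n
  x2 <- sum((abs(tab - expected) - 0.5)^2 / expected)
  expect_equal(st$p_mouse_homogeneity, 1 - pchisq(x2, df = 1), tolerance = 1e-12)
  expect_error(population_preference_stats(cl[1, ]), "at least 2")
})

test_that("baseline-rate grouping uses half-open decreasing intervals", {
  cl <- tibble::tibble(unit_id = sprintf("u%d", 1:6),
                       baseline_rate = c(0.5, 1, 4, 4.0, 9.9, 12))
  g <- group_by_baseline_rate(cl, edges = c(4))
  expect_identical(as.character(g$baseline_group),
                   c("bfr<4", "bfr<4", "bfr>=4", "bfr>=4", "bfr>=4", "bfr>=4"))
  g <- group_by_baseline_rate(cl, edges = c(10, 5, 1))
  expect_identical(as.character(g$baseline_group),
                   c("bfr<1", "5>bfr>=1", "5>bfr>=1", "5>bfr>=1",
                     "10>bfr>=5", "bfr>=10"))
  # all units in one group when edges exceed the max rate
  g <- group_by_baseline_rate(cl, edges = c(100))
  expect_true(all(g$baseline_group == "bfr<100"))
  expect_error(group_by_baseline_rate(cl, edges = c(1, 5)), "decreasing")
})

test_that("baseline-group summaries match a naive recomputation", {
  cl <- tibble::tibble(unit_id = sprintf("u%d", 1:8),
                       baseline_rate = c(0.2, 0.8, 2, 3, 6, 7, 11, 15))
  g <- group_by_baseline_rate(cl, edges = c(10, 5, 1))
  vals <- tibble::tibble(unit_id = cl$unit_id, value = c(1, 2, 3, 4, 5, 6, 7, 8))
  s <- baseline_group_summary(g, vals)
  expect_equal(nrow(s), 4)
  top <- s[s$baseline_group == "bfr>=10", ]
  expect_equal(top$n, 2L)
  expect_equal(top$mean, 7.5)
  expect_equal(top$sem, sd(c(7, 8)) / sqrt(2))
  # empty groups reported with n = 0
  g2 <- group_by_baseline_rate(cl[cl$baseline_rate < 5, ], edges = c(10, 5, 1))
  s2 <- baseline_group_summary(g2, vals)
  expect_equal(s2$n[s2$baseline_group == "bfr>=10"], 0L)
})
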