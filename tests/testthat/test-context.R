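test_that("identical feature distributions retain every trial", {
  tr <- tibble::tibble(run_speed = rep(c(1, 2, 3), 4), curvature = 0.005)
  oc <- occupancy_match(tr, tr, n_perm = 5)
  for (p in oc$plans) {
    expect_equal(sort(p$a), seq_len(nrow(tr)))
    expect_equal(sort(p$b), seq_len(nrow(tr)))
  }
})

test_that("disjoint feature supports are an error", {
  a <- tibble::tibble(run_speed = c(1, 1.1, 1.2), curvature = 0.005)
  b <- tibble::tibble(run_speed = c(9, 9.1, 9.2), curvature = 0.005)
  expect_error(occupancy_match(a, b, n_bins = 2), "disjoint")
  expect_error(occupancy_match(a, dplyr::mutate(b, run_speed = NA_real_)),
               "finite")
})

test_that("a two-bin toy retains the per-bin minimum in both conditions", {
  a <- tibble::tibble(run_speed = c(1, 1.2, 1.4, 1.6, 9))
  b <- tibble::tibble(run_speed = c(1.1, 1.3, 8.5, 8.8, 9))
  oc <- occupancy_match(a, b, features = "run_speed", n_bins = 2, n_perm = 4)
  for (p in oc$plans) {
    # bin 1 holds a: 4, b: 2 -> keep 2; bin 2 holds a: 1, b: 3 -> keep 1
    expect_equal(sum(a$run_speed[p$a] < 5), 2)
    expect_equal(sum(a$run_speed[p$a] > 5), 1)
    expect_equal(sum(b$run_speed[p$b] < 5), 2)
    expect_equal(sum(b$run_speed[p$b] > 5), 1)
  }
})

test_that("matched joint histograms are identical across conditions for all plans", {
  set.seed(30)
  for (rep in 1:5) {
    a <- tibble::tibble(run_speed = rnorm(60, 2), curvature = rnorm(60, 0, 0.01))
    b <- tibble::tibble(run_speed = rnorm(40, 2.5), curvature = rnorm(40, 0, 0.012))
    oc <- occupancy_match(a, b, n_bins = 4, n_perm = 6)
    cell <- function(tr, idx) {
      ra <- range(c(a$run_speed, b$run_speed)); rc <- range(c(a$curvature, b$curvature))
      ia <- findInterval(tr$run_speed[idx], seq(ra[1], ra[2], length.out = 5),
                         rightmost.closed = TRUE)
      ic <- findInterval(tr$curvature[idx], seq(rc[1], rc[2], length.out = 5),
                         rightmost.closed = TRUE)
      table(factor(ia, 1:4), factor(ic, 1:4))
    }
    for (p in oc$plans) {
      expect_equal(cell(a, p$a), cell(b, p$b))
    }
  }
})

test_that("condition modulation is null when the generator applies no gain", {
  g <- generate_session(
    generator_config(n_units = 20, n_trials = 150, miss_gain = 1,
                     away_evoked_gain = 1, away_baseline_gain = 1,
                     miss_coupling = 0, baseline_coupling = 0,
                     p_miss = 0.3),
    seed = 31)
  s <- g$session
  z <- zscore_tensor(rate_tensor(s), s)
  m <- condition_modulation(z, s, contrast = "Hit_vs_Miss", window = "evoked")
  expect_lt(mean(m$significant), 0.25)
  expect_lt(abs(mean(m$delta_z)), 0.3)
})

test_that("a halved Miss response is detected in most positive-preferring units", {
  # 80 Miss and 80 Hit trials (no Away blocks), solid baseline rates
  g <- generate_session(
    generator_config(n_units = 24, n_trials = 320, p_miss = 0.5,
                     miss_coupling = 0, frac_positive_preferring = 1,
                     baseline_median = 8, away_block = 1000),
    seed = 32)
  s <- g$session
  z <- zscore_tensor(rate_tensor(s), s)
  m <- condition_modulation(z, s, contrast = "Hit_vs_Miss", window = "evoked")
  expect_gt(mean(m$significant & m$delta_z < 0), 0.9)
  expect_lt(attr(m, "population_p"), 1e-4)
})

test_that("Away baseline suppression appears only in positive-preferring units", {
  # miss_coupling = 0 so Hit trials are not engagement-selected: otherwise
  # the Hit reference has higher baseline in every unit and the contrast is
  # no longer specific to the generated Away gain
  g <- generate_session(generator_config(n_units = 40, n_trials = 200,
                                         baseline_median = 8,
                                         miss_coupling = 0,
                                         baseline_coupling = 0), seed = 33)
  s <- g$session
  z <- zscore_tensor(rate_tensor(s), s)
  m <- condition_modulation(z, s, contrast = "Home_vs_Away", window = "baseline")
  truth <- g$truth$units
  pos <- m$unit_id %in% truth$unit_id[truth$preference == "positive"]
  frac_pos <- mean(m$significant[pos] & m$delta_z[pos] < 0)
  frac_neg <- mean(m$significant[!pos] & m$delta_z[!pos] < 0)
  expect_gt(frac_pos, 0.4)
  expect_lt(frac_neg, 0.15)
})

test_that("occupancy-matched statistics average over permutations and stabilize", {
  g <- generate_session(generator_config(n_units = 6, n_trials = 160,
                                         p_miss = 0.35, miss_coupling = 0),
                        seed = 34)
  s <- g$session
  z <- zscore_tensor(rate_tensor(s), s)
  tr <- s$trials
  miss <- tr[tr$outcome == "Miss" & tr$context == "Home", ]
  hit <- tr[tr$outcome == "Hit" & tr$context == "Home", ]
  deltas <- function(n_perm) {
    replicate(12, {
      plan <- occupancy_match(miss, hit, n_bins = 3, n_perm = n_perm)
      m <- condition_modulation(z, s, contrast = "Hit_vs_Miss",
                                window = "evoked", plan = plan)
      mean(m$delta_z)
    })
  }
  set.seed(35)
  v1 <- var(deltas(1))
  v20 <- var(deltas(20))
  expect_lt(v20, v1)
})

test_that("modulation fractions are a straight recount of the result table", {
  res <- tibble::tibble(
    unit_id = sprintf("u%d", 1:10),
    contrast = "Hit_vs_Miss", window = "evoked",
    delta_z = c(-1, -2, 0.5, -0.3, 1, -1, 2, -0.1, 0.2, -4),
    significant = c(TRUE, TRUE, TRUE, FALSE, FALSE, TRUE, TRUE, FALSE, FALSE, TRUE))
  rep <- modulation_fraction_report(res)
  expect_equal(rep$n_significant, 6)
  expect_equal(rep$fraction_significant, 0.6)
  expect_equal(rep$n_decreased, 4)
  expect_equal(rep$n_increased, 2)
  expect_error(modulation_fraction_report(res[0, ]), "nonempty")
  # 133 of 276 significant is the 48% reported for collicular Miss modulation
  big <- tibble::tibble(contrast = "Hit_vs_Miss", window = "evoked",
                        delta_z = -1,
                        significant = rep(c(TRUE, FALSE), c(133, 143)))
  expect_equal(round(100 * modulation_fraction_report(big)$fraction_significant),
               48)
})
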