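test_that("secretion trains are seeded, non-negative and empty without sources", {
  d <- quick_design()
  none <- generate_secretion_train(d, pulse_rate = 0, basal_rate = 0,
                                   seed = 1)
  expect_true(all(none$values == 0))
  a <- generate_secretion_train(d, pulse_rate = 12, seed = 99)
  b <- generate_secretion_train(d, pulse_rate = 12, seed = 99)
  expect_identical(a$values, b$values)
  expect_true(all(a$values >= 0))
  c <- generate_secretion_train(d, pulse_rate = 12, seed = 100)
  expect_false(identical(a$values, c$values))
  expect_error(generate_secretion_train(d, pulse_rate = -1), "pulse_rate")
  expect_error(generate_secretion_train(d, pulse_rate = 5, mass_cv = -0.1),
               "mass_cv")
})

test_that("pulse count follows the Poisson law and respects the refractory gap", {
  d <- quick_design()
  counts <- vapply(1:1000, function(s)
    sum(generate_secretion_train(d, pulse_rate = 12, seed = s)$values > 0),
    numeric(1))
  se <- sd(counts) / sqrt(length(counts))
  # refractory thinning removes a small expected fraction; stays within 3 SE
  expect_lt(abs(mean(counts) - 12), 3 * se)
  gaps <- vapply(1:200, function(s) {
    bins <- which(generate_secretion_train(d, pulse_rate = 20,
                                           seed = s)$values > 0)
    if (length(bins) < 2) Inf else min(diff(bins))
  }, numeric(1))
  expect_true(all(gaps >= 2))
})

test_that("positive coupling adds delayed pulses deterministically at strength 1", {
  d <- quick_design()
  drv <- fixed_train(c(10, 50, 144), masses = c(2, 1, 3))
  bg <- fixed_train(c(30))
  out <- couple_secretion(drv, coupling("h", "g", 3, "+", 1), bg, seed = 1)
  expect_equal(out$values[13], 2)   # 10 + 3
  expect_equal(out$values[53], 1)   # 50 + 3
  expect_equal(out$values[30], 1)   # background untouched
  expect_equal(sum(out$values > 0), 3)  # pulse at 144 truncated (147 > 145)
})

test_that("zero-strength coupling returns the background unchanged", {
  d <- quick_design()
  drv <- generate_secretion_train(d, 12, seed = 3)
  bg <- generate_secretion_train(d, 12, seed = 4)
  out <- couple_secretion(drv, coupling("h", "g", 5, "+", 0), bg, seed = 9)
  expect_identical(out$values, bg$values)
  out2 <- couple_secretion(drv, coupling("h", "g", 5, "-", 0), bg, seed = 9)
  expect_identical(out2$values, bg$values)
})

test_that("full-strength suppression empties the windows and spares the rest", {
  d <- quick_design()
  for (seed in 1:200) {
    drv <- generate_secretion_train(d, 12, seed = seed)
    bg <- generate_secretion_train(d, 12, seed = seed + 5000)
    out <- couple_secretion(drv, coupling("h", "g", 5, "-", 1), bg,
                            seed = seed + 10000, suppression_width = 3)
    n <- length(bg$values)
    win <- rep(FALSE, n)
    for (j in which(drv$values > 0)) {
      lo <- max(1, j + 4)
      hi <- min(n, j + 6)
      if (lo <= hi) win[lo:hi] <- TRUE
    }
    expect_true(all(out$values[win] == 0))
    expect_identical(out$values[!win], bg$values[!win])
  }
})

test_that("mismatched grids are rejected", {
  drv <- fixed_train(5, n = 100)
  bg <- fixed_train(5, n = 145)
  expect_error(couple_secretion(drv, coupling("h", "g", 1, "+", 1), bg),
               "grid")
})

test_that("concentration follows the exponential-decay closed form", {
  # single pulse of mass m at bin k decays as m * 2^(-j/6) for
  # half-life 60 min and a 10-min grid
  s <- fixed_train(21, masses = 1.7)
  conc <- secretion_to_concentration(s, elimination_model(60), noise_cv = 0)
  j <- 0:20
  expect_equal(conc$values[21 + j], 1.7 * 2^(-j / 6), tolerance = 1e-12)
  expect_equal(conc$values[20], 1e-6)  # detection floor before the pulse
  expect_equal(2^(-1 / 6), 0.8909, tolerance = 1e-4)

  # zero secretion with an initial concentration decays purely
  s0 <- fixed_train(integer(0))
  c0 <- secretion_to_concentration(s0, elimination_model(30,
                                     initial_concentration = 4),
                                   noise_cv = 0)
  t_idx <- 0:144
  expect_equal(c0$values, pmax(4 * 2^(-t_idx / 3), 1e-6), tolerance = 1e-12)
})

test_that("multiplicative noise reproduces the requested CV", {
  s <- fixed_train(c(20, 60, 100), masses = c(2, 2, 2))
  elim <- elimination_model(60)
  bin <- 70  # decently high level
  vals <- vapply(1:1000, function(seed)
    secretion_to_concentration(s, elim, noise_cv = 0.05,
                               seed = seed)$values[bin],
    numeric(1))
  expect_equal(sd(vals) / mean(vals), 0.05, tolerance = 0.008)
})

test_that("the forward model is linear in secretion", {
  d <- quick_design()
  s1 <- generate_secretion_train(d, 10, seed = 21)
  s2 <- generate_secretion_train(d, 10, seed = 22)
  sum12 <- secretion_series(s1$values + s2$values)
  elim <- elimination_model(45)
  c1 <- secretion_to_concentration(s1, elim, noise_cv = 0,
                                   detection_limit = 0)
  c2 <- secretion_to_concentration(s2, elim, noise_cv = 0,
                                   detection_limit = 0)
  c12 <- secretion_to_concentration(sum12, elim, noise_cv = 0,
                                    detection_limit = 0)
  expect_equal(c12$values, c1$values + c2$values, tolerance = 1e-12)
})

test_that("coupled secretion trains cross-correlate at the planted delay", {
  d <- quick_design()
  hits <- 0
  for (seed in 1:50) {
    drv <- generate_secretion_train(d, 16, seed = seed)
    bg <- generate_secretion_train(d, 16, seed = seed + 700)
    tgt <- couple_secretion(drv, coupling("h", "g", 4, "+", 0.9), bg,
                            seed = seed + 1400)
    ccf <- cross_correlation(drv, tgt, max_lag = 24)
    peak <- ccf$lags[which.max(ccf$values)]
    hits <- hits + (peak == 4)
  }
  expect_gte(hits, 45)  # >= 90% of seeds
})

test_that("cohorts have the right shape, determinism and altered-coupling checks", {
  truth <- ground_truth_network(hormones = c("X", "Y"))
  des <- study_design(n_subjects = 2)
  sim <- simulate_cohort(truth, des, seed = 5)
  counts <- table(sim$concentrations$subject_id,
                  sim$concentrations$hormone,
                  sim$concentrations$occasion)
  expect_equal(length(counts), 8)          # 2 x 2 x 2 series
  expect_true(all(counts == 145))
  sim2 <- simulate_cohort(truth, des, seed = 5)
  expect_identical(sim$concentrations, sim2$concentrations)
  expect_identical(sim$secretions, sim2$secretions)
  expect_error(
    simulate_cohort(truth, des, altered = list(coupling("X", "Z", 1, "+")),
                    seed = 5),
    "unknown hormone")
  # no altered list: both occasions share the generating truth
  expect_identical(sim$truth$couplings$before, sim$truth$couplings$after)
})

test_that("series values respect the non-negativity and floor invariants", {
  truth <- ground_truth_network(hormones = c("X", "Y", "Z"),
    couplings = list(coupling("X", "Y", 2, "-", 0.8)))
  sim <- simulate_cohort(truth, study_design(n_subjects = 3), seed = 11)
  expect_true(all(sim$secretions$value >= 0))
  expect_true(all(sim$concentrations$value >= 1e-6))
})
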