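subject_ccf_fixture <- function(n_subjects, lags = -6:6, seed = 1,
                                shift = 0) {
  set.seed(seed)
  M <- matrix(runif(n_subjects * length(lags), -0.3, 0.3),
              nrow = n_subjects)
  colnames(M) <- lags
  M[, match(shift, lags)] <- M[, match(shift, lags)] + 0.4
  M
}

test_that("cohort-average CCF matches direct recomputation", {
  M <- subject_ccf_fixture(18, seed = 31)
  cfg_raw <- analysis_config(fisher_transform = FALSE)
  expect_equal(mean_ccf(M, cfg_raw)$values, unname(colMeans(M)),
               tolerance = 1e-12)
  cfg_z <- analysis_config(fisher_transform = TRUE)
  expect_equal(mean_ccf(M, cfg_z)$values,
               unname(tanh(colMeans(atanh(M)))), tolerance = 1e-12)
  # identical subjects average to themselves
  M1 <- M[rep(1, 6), ]
  expect_equal(mean_ccf(M1, cfg_z)$values, unname(M[1, ]),
               tolerance = 1e-12)
  # opposite pair averages to zero in raw mode
  M2 <- rbind(M[1, ], -M[1, ], M[1, ], -M[1, ])
  colnames(M2) <- colnames(M)
  expect_equal(max(abs(mean_ccf(M2, cfg_raw)$values)), 0, tolerance = 1e-15)
  # lags with fewer than three defined subjects are undefined
  M3 <- M
  M3[3:18, 3] <- NA
  expect_true(is.na(mean_ccf(M3, cfg_z)$values[3]))
})

test_that("optima are located by brute-force scan with stated tie-breaks", {
  set.seed(32)
  for (rep in 1:25) {
    vals <- runif(49, -0.5, 0.5)
    ccf <- structure(list(lags = -24:24, values = vals, tau_minutes = 10),
                     class = "ccf_fn")
    opt <- find_optima(ccf, analysis_config())
    if (any(vals > 0))
      expect_equal(opt$positive$value, max(vals))
    if (any(vals < 0))
      expect_equal(opt$negative$value, min(vals))
  }
  # strictly positive: no negative optimum
  ccf <- structure(list(lags = -3:3, values = rep(0.2, 7), tau_minutes = 10),
                   class = "ccf_fn")
  expect_null(find_optima(ccf, analysis_config())$negative)
  # exact tie at -2 and +2: positive lag wins
  vals <- c(0.1, 0.5, 0.1, 0.1, 0.1, 0.5, 0.1)
  ccf <- structure(list(lags = -3:3, values = vals, tau_minutes = 10),
                   class = "ccf_fn")
  expect_equal(find_optima(ccf, analysis_config())$positive$lag, 2)
  # tie between |lag| 1 and 3: smaller |lag| wins
  vals2 <- c(0, 0, 0.5, 0.2, 0, 0, 0.5)
  ccf2 <- structure(list(lags = -3:3, values = vals2, tau_minutes = 10),
                    class = "ccf_fn")
  expect_equal(find_optima(ccf2, analysis_config())$positive$lag, -1)
  # all undefined: both optima absent
  ccf3 <- structure(list(lags = -3:3, values = rep(NA_real_, 7),
                         tau_minutes = 10), class = "ccf_fn")
  opt3 <- find_optima(ccf3, analysis_config())
  expect_null(opt3$positive)
  expect_null(opt3$negative)
})

test_that("leave-two-out robustness enumerates all subject pairs", {
  M <- subject_ccf_fixture(18, seed = 33, shift = 2)
  rb <- leave_two_out_robustness(M, sign = "+", analysis_config())
  expect_equal(rb$n_resamples, choose(18, 2))  # 153
  expect_equal(length(rb$resample_lags), 153)
  # identical subjects: every resample finds the same optimum
  M1 <- M[rep(3, 10), ]
  rb1 <- leave_two_out_robustness(M1, sign = "+", analysis_config())
  expect_equal(rb1$modal_fraction, 1)
  expect_true(rb1$robust)
  expect_error(leave_two_out_robustness(M[1:4, ], "+", analysis_config()),
               "5 subjects")
})

test_that("relation test follows the optimum's direction", {
  vals <- rep(0, 10)
  expect_equal(as.numeric(test_relation(vals, "+")), 0.5)
  set.seed(34)
  strong <- rnorm(18, 0.5, 0.1)
  expect_lt(as.numeric(test_relation(strong, "+")), 1e-4)
  expect_gt(as.numeric(test_relation(strong, "-")), 0.999)
})

test_that("directionality is NA at lag 0 and 0.5 when lags carry no signal", {
  M <- subject_ccf_fixture(12, seed = 35, shift = 3)
  expect_true(is.na(test_directionality(M, 0L)))
  # r(k*) identical to r(0) for every subject: no evidence of delay
  M2 <- M
  M2[, match(3, colnames(M2))] <- M2[, match(0, colnames(M2))]
  expect_equal(test_directionality(M2, 3L), 0.5)
  # r(k*) clearly exceeds r(0): directed
  M3 <- M
  M3[, match(3, colnames(M3))] <- 0.6
  M3[, match(0, colnames(M3))] <- 0.05
  expect_lt(test_directionality(M3, 3L), 0.01)
})

test_that("candidate re-expression is an involution onto non-negative lags", {
  cases <- list(c("a", "b", -5L), c("a", "b", 0L), c("x", "y", 7L))
  for (cs in cases) {
    lag <- as.integer(cs[3])
    once <- orient_candidate(cs[1], cs[2], lag)
    expect_gte(once$lag_tau, 0)
    # map back with the sign restored, then forward again
    back_lag <- if (lag < 0) -once$lag_tau else once$lag_tau
    twice <- orient_candidate(
      if (lag < 0) once$target else once$source,
      if (lag < 0) once$source else once$target,
      back_lag)
    expect_identical(orient_candidate(twice$source, twice$target,
                                      twice$lag_tau)$lag_tau,
                     abs(lag))
  }
})

test_that("planted couplings are recovered with sign, lag and directionality", {
  truth <- ground_truth_network(
    hormones = c("A", "B", "C", "D", "E", "F"),
    couplings = list(coupling("A", "B", 3, "+", 0.9),
                     coupling("C", "D", 5, "-", 0.9)))
  hits_ab <- 0
  hits_cd <- 0
  directed_ab <- 0
  for (seed in 1:5) {
    sim <- simulate_cohort(truth, study_design(n_subjects = 18,
                                               occasions = "before"),
                           seed = seed + 900)
    net <- infer_dynamic_network(sim$secretions)
    ed <- network_edges(net)
    ab <- ed[ed$source == "A" & ed$target == "B" & ed$sign == "+" &
               abs(ed$lag_tau - 3) <= 1, ]
    cd <- ed[ed$source == "C" & ed$target == "D" & ed$sign == "-" &
               abs(ed$lag_tau - 5) <= 1, ]
    hits_ab <- hits_ab + (nrow(ab) > 0)
    hits_cd <- hits_cd + (nrow(cd) > 0)
    directed_ab <- directed_ab + (nrow(ab) > 0 && any(ab$directed))
  }
  expect_gte(hits_ab, 5)
  expect_gte(hits_cd, 4)
  expect_gte(directed_ab, 5)
})

test_that("every reported edge satisfies the record invariants", {
  truth <- ground_truth_network(
    hormones = c("A", "B", "C", "D"),
    couplings = list(coupling("A", "B", 0, "+", 0.9),
                     coupling("B", "C", 4, "+", 0.8)))
  sim <- simulate_cohort(truth, study_design(n_subjects = 18,
                                             occasions = "before"),
                         seed = 1001)
  net <- infer_dynamic_network(sim$secretions)
  tab <- net$table
  expect_true(all(tab$lag_tau >= 0))
  expect_true(all(tab$sign %in% c("+", "-")))
  expect_true(all(abs(tab$mean_assoc) <= 1))
  expect_true(all(tab$mean_assoc[tab$sign == "+"] > 0))
  expect_true(all(tab$mean_assoc[tab$sign == "-"] < 0))
  expect_true(all(tab$q_relation >= tab$p_relation - 1e-15))
  # directionality is not-applicable exactly for lag-0 rows (significant
  # rows carry a value otherwise)
  sig <- tab[tab$significant, ]
  expect_true(all(is.na(sig$p_directionality[sig$lag_tau == 0])))
  expect_true(all(!is.na(sig$p_directionality[sig$lag_tau > 0])))
  # lag-0 relations appear under both presentation orders, sharing a test
  lag0 <- tab[tab$lag_tau == 0, ]
  if (nrow(lag0) > 0) {
    expect_true(all(table(lag0$test_id) == 2))
    for (id in unique(lag0$test_id)) {
      two <- lag0[lag0$test_id == id, ]
      expect_identical(two$source[1], two$target[2])
      expect_equal(two$p_relation[1], two$p_relation[2])
    }
  }
})

test_that("power to recover a planted edge grows with coupling strength", {
  recover_rate <- function(strength, seeds) {
    truth <- ground_truth_network(
      hormones = c("A", "B", "C", "D"),
      couplings = list(coupling("A", "B", 3, "+", strength)))
    hits <- 0
    for (seed in seeds) {
      sim <- simulate_cohort(truth, study_design(n_subjects = 18,
                                                 occasions = "before"),
                             seed = seed)
      ed <- network_edges(infer_dynamic_network(sim$secretions),
                          require_robust = FALSE)
      hits <- hits + (nrow(ed[ed$source == "A" & ed$target == "B" &
                                ed$sign == "+" &
                                abs(ed$lag_tau - 3) <= 1, ]) > 0)
    }
    hits / length(seeds)
  }
  seeds <- 2001:2012
  r_weak <- recover_rate(0.2, seeds)
  r_mid <- recover_rate(0.5, seeds)
  r_strong <- recover_rate(0.9, seeds)
  expect_gte(r_mid, r_weak - 1 / length(seeds))
  expect_gte(r_strong, r_mid - 1 / length(seeds))
  expect_gte(r_strong, 0.9)
})

test_that("null relation p-values are calibrated at a fixed lag", {
  # with no optimum search the one-sided relation test is uniform under
  # independence across subjects
  ps <- numeric(150)
  d <- quick_design()
  for (rep in 1:150) {
    r <- vapply(1:10, function(s) {
      x <- generate_secretion_train(d, 16, seed = rep * 37 + s)$values
      y <- generate_secretion_train(d, 16, seed = 100000 + rep * 41 + s)$values
      hormonet:::ccf_at_lag(x, y, 3)
    }, numeric(1))
    ps[rep] <- as.numeric(test_relation(r, "+"))
  }
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})

test_that("uncorrected optimum testing is anticonservative under the null", {
  # rationale for the default search correction: testing the selected
  # optimum directly discovers far more than alpha_dynamic on
  # independent hormones, even at the stricter 1% level
  truth <- ground_truth_network(hormones = c("A", "B", "C", "D", "E", "F"))
  des <- study_design(n_subjects = 18, occasions = "before")
  cfg_none <- analysis_config(optimum_correction = "none")
  cand <- 0
  sig <- 0
  for (seed in 1:40) {
    secr <- simulate_cohort(truth, des, seed = seed + 9500)$secretions
    tab <- infer_dynamic_network(secr, cfg_none)$table
    tab <- tab[!duplicated(tab$test_id), ]
    cand <- cand + nrow(tab)
    sig <- sig + sum(tab$significant)
  }
  expect_gt(sig / cand, 3 * cfg_none$alpha_dynamic)
})

test_that("treatment flags respect the significance and tendency bands", {
  q <- c(0.01, 0.05, 0.0501, 0.07, 0.0999, 0.10, 0.2, NA)
  expect_identical(treatment_flags(q),
                   c("significant", "significant", "tendency", "tendency",
                     "tendency", "none", "none", NA))
})

test_that("identical occasions produce no treatment flags", {
  truth <- ground_truth_network(
    hormones = c("A", "B", "C", "D"),
    couplings = list(coupling("A", "B", 3, "+", 0.9)))
  sim <- simulate_cohort(truth, study_design(n_subjects = 18,
                                             occasions = "before"),
                         seed = 1101)
  net <- infer_dynamic_network(sim$secretions)
  ed <- network_edges(net)
  out <- test_treatment_effect(sim$secretions, sim$secretions, ed)
  expect_true(all(out$p_treatment == 1))
  expect_true(all(abs(out$delta_assoc) < 1e-12))
  expect_true(all(out$treatment_flag == "none"))
})

test_that("a removed coupling is flagged and unchanged ones are not", {
  truth <- ground_truth_network(
    hormones = c("A", "B", "C", "D", "E", "F"),
    couplings = list(coupling("A", "B", 3, "+", 0.9),
                     coupling("C", "D", 5, "-", 0.9)))
  altered <- list(coupling("C", "D", 5, "-", 0.9))
  flagged <- 0
  kept_quiet <- 0
  n_kept <- 0
  for (seed in 1:6) {
    sim <- simulate_cohort(truth, study_design(n_subjects = 18),
                           altered = altered, seed = seed + 1200)
    before <- sim$secretions[sim$secretions$occasion == "before", ]
    after <- sim$secretions[sim$secretions$occasion == "after", ]
    ed <- network_edges(infer_dynamic_network(before, occasion = "before"))
    out <- test_treatment_effect(before, after, ed)
    ab <- out[out$source == "A" & out$target == "B" & out$sign == "+", ]
    cd <- out[out$source == "C" & out$target == "D" & out$sign == "-", ]
    if (nrow(ab) > 0)
      flagged <- flagged + any(ab$treatment_flag == "significant")
    if (nrow(cd) > 0) {
      n_kept <- n_kept + 1
      kept_quiet <- kept_quiet +
        all(cd$treatment_flag != "significant")
    }
  }
  expect_gte(flagged, 5)
  expect_gte(kept_quiet, n_kept - 1)
})

test_that("treatment testing drops incomplete subjects pairwise", {
  truth <- ground_truth_network(hormones = c("A", "B", "C"),
    couplings = list(coupling("A", "B", 2, "+", 0.9)))
  sim <- simulate_cohort(truth, study_design(n_subjects = 8),
                         seed = 1301)
  before <- sim$secretions[sim$secretions$occasion == "before", ]
  after <- sim$secretions[sim$secretions$occasion == "after", ]
  after_missing <- after[after$subject_id != "s01", ]
  ed <- network_edges(infer_dynamic_network(before, occasion = "before"))
  expect_warning(out <- test_treatment_effect(before, after_missing, ed),
                 "dropped")
  expect_equal(nrow(out), nrow(ed))
})
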