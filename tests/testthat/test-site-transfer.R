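test_that("apparent transfer probability follows the band-fraction formula", {
  expect_equal(compute_ptrans_obs(0.3, 0.3, 0.1, 0.1), 0.5)
  expect_equal(compute_ptrans_obs(0.2, 0.2, 0.2, 0.2), 0)   # no-transfer symmetry
  expect_equal(compute_ptrans_obs(0.4, 0.3, 0, 0), 1)       # all-double limit
  expect_true(is.na(compute_ptrans_obs(0, 0, 0, 0)))        # undefined, not zero
  # scale invariance: common lane-loading factor drops out
  expect_equal(compute_ptrans_obs(0.3, 0.25, 0.1, 0.15),
               compute_ptrans_obs(3.0, 2.5, 1.0, 1.5))
})

test_that("zero-time extrapolation recovers exact lines and flags bad input", {
  const <- extrapolate_zero_time(c(0.42, 0.42, 0.42), c(1, 2, 3))
  expect_equal(const$P_trans, 0.42, tolerance = 1e-12)
  expect_equal(const$slope, 0, tolerance = 1e-12)

  line <- extrapolate_zero_time(c(0.30, 0.35, 0.40), c(1, 2, 3))
  expect_equal(line$P_trans, 0.25, tolerance = 1e-12)

  expect_error(extrapolate_zero_time(c(0.3, 0.4), c(1, 2)), "3 valid timepoints")
  expect_warning(
    expect_equal(
      extrapolate_zero_time(c(0.30, NA, 0.35, 0.40), c(1, 1.5, 2, 3))$P_trans,
      0.25, tolerance = 1e-12),
    "excluded")
})

test_that("Eq.-1 estimator is unbiased across transfer levels without rebinding", {
  levels <- c(0, 0.34, 0.5, 0.8, 1)
  for (P in levels) {
    est <- vapply(1:200, function(s) {
      tc <- simulate_population(population_config(n = 400, rebind = 0, seed = s),
                                true_P_trans = P)
      mean(compute_ptrans_obs(tc$A, tc$C, tc$AB, tc$BC), na.rm = TRUE)
    }, numeric(1))
    se_mean <- stats::sd(est) / sqrt(length(est))
    expect_lt(abs(mean(est) - P), 2 * se_mean + 1e-12)
  }
})

test_that("zero-time intercept removes at least 5x more rebinding bias than the last timepoint", {
  P <- 0.34
  res <- t(vapply(1:30, function(s) {
    tc <- simulate_population(
      population_config(n = 2000, rebind = 0.004, seed = s), true_P_trans = P)
    ta <- transfer_analysis(tc)
    c(ta$P_trans, ta$p_obs[length(ta$p_obs)])
  }, numeric(2)))
  bias_int <- abs(mean(res[, 1]) - P)
  bias_last <- abs(mean(res[, 2]) - P)
  expect_gt(bias_last, 5 * bias_int)
})

test_that("pathway partition is exact, propagates error, and matches event logs", {
  p <- partition_pathways(P_trans = 0.8, P_assoc = 0.7,
                          se_trans = 0.03, se_assoc = 0.04)
  expect_equal(p$P_diss, 0.1, tolerance = 1e-12)
  expect_equal(p$se, 0.05, tolerance = 1e-12)
  expect_equal(partition_pathways(0.5, 0.5)$P_diss, 0)
  expect_warning(partition_pathways(0.4, 0.6, 0.01, 0.01), "exceeds")

  # trap-off overall minus trap-on associative equals the dissociative
  # fraction counted directly from the walker's event logs
  cfg <- walker_config(spacing = 10, q = 0.01, n = 20000, seed = 9,
                       trap_on = FALSE, p_return = 0.7)
  w_off <- simulate_walker(cfg)
  cfg_on <- cfg; cfg_on$trap_on <- TRUE
  w_on <- simulate_walker(cfg_on)
  pd <- partition_pathways(w_off$p_transfer[["estimate"]],
                           w_on$p_transfer[["estimate"]],
                           w_off$p_transfer[["se"]],
                           w_on$p_transfer[["se"]])
  diss_logged <- w_off$p_diss[["estimate"]]  # hop-containing successful paths
  expect_lt(abs(pd$P_diss - diss_logged), 3 * pd$se)
})

test_that("efficiency correction rescales and flags inconsistency", {
  expect_equal(correct_efficiency(0.4, E = 0.81)$P_trans_true, 0.4 / 0.81,
               tolerance = 1e-12)
  expect_equal(correct_efficiency(0.7, E = 1)$P_trans_true, 0.7)
  expect_warning(out <- correct_efficiency(0.95, E = 0.92), "exceeds 1")
  expect_true(out$flagged)
  expect_error(correct_efficiency(0.5, E = 0), "E must")
})

test_that("transfer analysis of a simulated course recovers the generator truth", {
  tc <- simulate_population(population_config(n = 10000, rebind = 0.002, seed = 5),
                            true_P_trans = 0.34)
  ta <- transfer_analysis(tc)
  expect_lt(abs(ta$P_trans - 0.34), 3 * ta$se)
  # the last timepoint overshoots the intercept under rebinding
  expect_gt(ta$p_obs[length(ta$p_obs)], ta$P_trans)
  # extent-regressor variant is available and behaves sanely
  ta2 <- transfer_analysis(tc, regressor = "extent")
  expect_lt(abs(ta2$P_trans - 0.34), 0.05)
})
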