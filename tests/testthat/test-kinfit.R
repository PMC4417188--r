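test_that("second-order fit recovers generator k_on from noiseless traces", {
  for (par in list(c(k_on = 2.7e9, tmax = 0.02), c(k_on = 3e8, tmax = 1))) {
    tr <- simulate_association_trace(par[["k_on"]], 200e-9, Y0 = 0.2, Yf = 1.2,
                                     times = seq(0, par[["tmax"]],
                                                 length.out = 300))
    fit <- fit_second_order(tr)
    expect_equal(unname(fit$parameters["k_on"]), par[["k_on"]],
                 tolerance = 1e-6)
  }
})

test_that("second-order fit handles noise and rejects flat traces", {
  tr <- simulate_association_trace(2.7e9, 200e-9, 0, 1,
                                   times = seq(0, 0.02, length.out = 300),
                                   noise_sd = 0.01, seed = 4)
  fit <- fit_second_order(tr)
  expect_lt(abs(fit$parameters[["k_on"]] / 2.7e9 - 1), 0.05)
  flat <- kinetic_trace(seq(0, 1, length.out = 50), rep(1, 50), P0 = 1e-7)
  expect_error(fit_second_order(flat), "zero-amplitude")
})

test_that("fit is invariant to time and concentration unit rescaling", {
  # s -> ms and M -> nM leave the dimensionless product k_on * P0 * t alone
  t_s <- seq(0, 0.02, length.out = 200)
  tr <- simulate_association_trace(2.7e9, 200e-9, 0, 1, times = t_s)
  k1 <- fit_second_order(tr)$parameters[["k_on"]]
  tr_ms <- kinetic_trace(t_s * 1000, tr$signal, P0 = 200e-9 / 1000)
  k2 <- fit_second_order(tr_ms)$parameters[["k_on"]]
  expect_equal(k1 * 200e-9 * 0.02, k2 * 200e-12 * 20, tolerance = 1e-6)
})

test_that("exponential fitting selects the right model and recovers rates", {
  d1 <- simulate_dissociation_trace(1.01, 1, times = seq(0, 6, length.out = 300))
  f1 <- fit_exponentials(d1)
  expect_identical(f1$selected_components, 1L)
  expect_equal(unname(f1$parameters["k1"]), 1.01, tolerance = 1e-7)

  d2 <- simulate_dissociation_trace(c(0.35, 0.024), c(0.56, 0.44),
                                    times = seq(0, 200, length.out = 500))
  f2 <- fit_exponentials(d2)
  expect_identical(f2$selected_components, 2L)
  expect_equal(unname(f2$parameters["k_fast"]), 0.35, tolerance = 1e-6)
  expect_equal(unname(f2$parameters["k_slow"]), 0.024, tolerance = 1e-6)
  expect_equal(f2$slow_fraction, 0.44, tolerance = 1e-6)
  expect_gt(f2$parameters[["k_fast"]], f2$parameters[["k_slow"]])

  flat <- kinetic_trace(seq(0, 5, length.out = 60), rep(2, 60))
  expect_error(fit_exponentials(flat), "zero-amplitude")
})

test_that("AICc does not overfit single-exponential data at SNR 20", {
  correct <- vapply(1:50, function(s) {
    d <- simulate_dissociation_trace(1, 1, times = seq(0, 6, length.out = 200),
                                     noise_sd = 0.05, seed = s)
    fit_exponentials(d)$selected_components == 1L
  }, logical(1))
  expect_gte(mean(correct), 0.95)
})

test_that("Michaelis-Menten fitting recovers parameters and refuses bad designs", {
  S <- c(10, 25, 50, 100, 200, 400) * 1e-9
  rt <- simulate_initial_rates(2.1, 50e-9, 1e-9, S)
  m <- fit_michaelis_menten(rt, E0 = 1e-9)
  expect_equal(m$k_cat, 2.1, tolerance = 1e-7)
  expect_equal(m$K_m, 50e-9, tolerance = 1e-6)
  expect_equal(m$k_cat_over_K_m, 2.1 / 50e-9, tolerance = 1e-6)

  # relative parameters: crowded / buffer ratio
  rt_peg <- simulate_initial_rates(1.2, 200e-9, 1e-9, S)
  m_peg <- fit_michaelis_menten(rt_peg, E0 = 1e-9)
  rel <- relative_params(m_peg, m)
  expect_equal(rel$k_cat_rel, 1.2 / 2.1, tolerance = 1e-6)

  # kcat-only mode: saturating rates must agree
  sat <- data.frame(conc_M = c(2e-6, 4e-6), rate_Ms = c(2.05e-9, 2.1e-9))
  expect_equal(fit_michaelis_menten(sat, E0 = 1e-9, mode = "kcat_only")$k_cat,
               mean(c(2.05, 2.1)), tolerance = 1e-9)
  bad <- data.frame(conc_M = c(2e-6, 4e-6), rate_Ms = c(1.0e-9, 2.1e-9))
  expect_error(fit_michaelis_menten(bad, E0 = 1e-9, mode = "kcat_only"),
               "refuses")

  # all [S] << K_m leaves K_m unidentifiable
  rt_low <- simulate_initial_rates(2.1, 1e-5, 1e-9, S = c(1, 2, 4, 8, 16) * 1e-9)
  expect_warning(fit_michaelis_menten(rt_low, E0 = 1e-9), "unidentifiable")
})

test_that("isotherm fit recovers K_D and detects degenerate titrations", {
  ti <- simulate_titration(1.3e-6, titration_design())
  fit <- fit_titration(ti)
  expect_equal(fit$K_D, 1.3e-6, tolerance = 1e-6)
  # ligand depletion round trip
  ti_dep <- simulate_titration(1.3e-6, titration_design(), L0 = 0.5e-6)
  expect_equal(fit_titration(ti_dep, L0 = 0.5e-6)$K_D, 1.3e-6, tolerance = 1e-5)
  flat <- data.frame(conc_M = titration_design(),
                     anisotropy = rep(0.1, 12))
  expect_error(fit_titration(flat), "zero-amplitude")
})

test_that("ISE slopes and the activity-coefficient ratio are recovered", {
  d <- simulate_ise_standards(49, intercept = 10)
  p <- simulate_ise_standards(41, intercept = 12)
  pair <- fit_ise_pair(d, p)
  expect_equal(pair$dilute$slope, 49, tolerance = 1e-9)
  expect_equal(pair$crowded$slope, 41, tolerance = 1e-9)
  expect_equal(pair$activity_ratio, 41 / 49, tolerance = 1e-9)
  expect_error(fit_ise(data.frame(conc = c(1, 10), mV = c(0, 49))), ">= 4")
})

test_that("kinetic K_D from rate constants lands at sub-nanomolar affinity", {
  kd <- kd_kinetic(1.01, 2.7e9, se_k_off = 0.05, se_k_on = 0.3e9)
  expect_equal(kd$K_D * 1e9, 0.374, tolerance = 1e-2)
  # same order of magnitude as the equilibrium value of ~0.3 nM
  expect_true(kd$K_D > 1e-10 && kd$K_D < 1e-9)
  expect_gt(kd$se, 0)
})
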