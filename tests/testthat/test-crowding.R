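test_that("PEG radius-of-gyration law reproduces the known coil sizes", {
  expect_equal(round(rg_peg(8000), 1), 4.1)
  expect_equal(round(rg_peg(600), 1), 0.9)
  expect_equal(rg_peg(8000) / rg_peg(600), 4.5, tolerance = 0.02)
  expect_error(rg_peg(50), "calibrated")
  # exact power law: log-log slope is the exponent everywhere
  mw <- c(300, 1e3, 8e3, 1e5, 9e5)
  slopes <- diff(log(rg_peg(mw))) / diff(log(mw))
  expect_equal(slopes, rep(0.583, 4), tolerance = 1e-12)
})

test_that("depletion layer equals R_g in the dilute regime and grows with M_w", {
  p8k <- polymer_spec("PEG 8K", 8000, percent_wv = 20, eta_rel = 13)
  expect_equal(depletion_layer(p8k), rg_peg(8000))
  expect_equal(round(depletion_layer(p8k), 1), 4.1)
  mw <- c(600, 1500, 3350, 8000)
  d <- vapply(mw, function(m) depletion_layer(polymer_spec("PEG", m)),
              numeric(1))
  expect_true(all(diff(d) > 0))
})

test_that("encounter distance reconstruction reaches ~11 nm for PEG 8K", {
  enc <- encounter_distance(polymer_spec("PEG 8K", 8000),
                            r_protein = 2.0, r_dna = 1.0)
  expect_equal(enc$distance_nm, 11.2, tolerance = 0.05)
  expect_match(enc$formula, "reconstruction")
})

test_that("kinetic partition of P_diss computes, bounds, and errors correctly", {
  expect_equal(pdiss_partition(1, 1, 1, 1), 0.25)
  expect_equal(pdiss_partition(2, 8, 9, 1), 0.18, tolerance = 1e-12)
  expect_lt(pdiss_partition(1, 1e9, 1, 1), 1e-8)  # pure-associative limit
  expect_error(pdiss_partition(0, 0, 1, 1), "undefined")
  expect_error(pdiss_partition(-1, 1, 1, 1))
})

test_that("P_diss is monotone in each rate and always a probability", {
  grid <- expand.grid(k_off = c(0.5, 2, 8), k_assoc = c(0.5, 2, 8),
                      k_return = c(0.5, 2, 8), k_bulk = c(0.5, 2, 8))
  p <- mapply(pdiss_partition, grid$k_off, grid$k_assoc,
              grid$k_return, grid$k_bulk)
  expect_true(all(p >= 0 & p <= 1))
  base <- pdiss_partition(1, 2, 3, 4)
  expect_gt(pdiss_partition(2, 2, 3, 4), base)   # increasing in k_off
  expect_lt(pdiss_partition(1, 4, 3, 4), base)   # decreasing in k_assoc
  expect_gt(pdiss_partition(1, 2, 6, 4), base)   # increasing in k_return
  expect_lt(pdiss_partition(1, 2, 3, 8), base)   # decreasing in k_bulk
})

test_that("opposing crowding shifts can cancel in P_diss while each term moves", {
  # scaling both the associative step rate and the return rate by c > 1
  # (what a crowder does) can leave P_diss nearly unchanged even though the
  # dissociation bracket alone drops substantially
  found <- FALSE
  for (ka in c(1, 2, 4)) {
    for (kb in c(2, 4, 8)) {
      for (cc in c(1.5, 2, 3)) {
        p0 <- pdiss_partition(1, ka, 1, kb)
        p1 <- pdiss_partition(1, ka * cc, cc, kb)
        b0 <- 1 / (1 + ka); b1 <- 1 / (1 + ka * cc)
        if (abs(p1 / p0 - 1) < 0.10 && abs(b1 / b0 - 1) > 0.30) found <- TRUE
      }
    }
  }
  expect_true(found)
})

test_that("Stokes-Einstein deviation table classifies conditions correctly", {
  tab <- data.frame(
    condition = c("buffer", "PEG8K_20", "ideal_viscogen", "slow"),
    k_on = c(2.7e9, 3e8, 2.7e9 / 5, 2.7e9 / 30),
    eta_rel = c(1, 13, 5, 20))
  out <- se_deviation(tab)
  expect_equal(out$tau_rel[1], 1)
  expect_equal(out$deviation[1], 0)
  expect_equal(out$tau_rel[2], 9)       # 2.7e9 / 3e8
  expect_identical(out$class[2], "negative")  # faster than viscosity predicts
  expect_identical(out$class[3], "SE-ideal")
  expect_identical(out$class[4], "positive")
  expect_error(se_deviation(tab[-1, ]), "buffer")
})

test_that("the packaged viscosity table loads with the crowding standard", {
  tab <- read_viscosity_table()
  row <- tab[tab$polymer == "PEG 8K" & tab$percent_wv == 20, ]
  expect_equal(row$eta_rel, 13)
  expect_true(all(tab$eta_rel >= 1))
})
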