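test_that("first-passage oracle matches hand-solved and limiting cases", {
  # adjacent target, no dissociation: certain absorption
  expect_equal(first_passage_oracle(spacing = 1, q = 0), 1.0)
  # spacing 2, q = 0.5, reflecting at the start: one-unknown system.
  # u(1) = 0.25 (u(0) + 1), u(0) = 0.5 u(1)  =>  u(1) = 2/7, u(0) = 1/7
  expect_equal(first_passage_oracle(spacing = 2, q = 0.5, left_extent = 0),
               1 / 7, tolerance = 1e-12)
  # strictly decreasing in q at fixed spacing (stochastic dominance)
  qs <- c(0.001, 0.005, 0.02, 0.1, 0.4)
  for (sp in c(2, 5, 15)) {
    p <- vapply(qs, function(q) first_passage_oracle(sp, q, 50), numeric(1))
    expect_true(all(diff(p) < 0), info = paste("spacing", sp))
  }
})

test_that("oracle rejects degenerate inputs", {
  expect_error(first_passage_oracle(0, 0.1), "spacing")
  expect_error(first_passage_oracle(5, 1), "q must")
  expect_error(first_passage_oracle(5, -0.1), "q must")
})

test_that("walker config rejects impossible parameterizations", {
  expect_error(sim_config(site1_pos = 50, site2_pos = 50), "site")
  expect_error(sim_config(q = 0, p_return = 1), "never terminate")
  expect_error(sim_config(q = 1.5), "probabilities")
  expect_error(sim_config(timepoints = c(3, 2, 1)), "increasing")
})

test_that("adjacent sites with negligible dissociation transfer almost surely", {
  cfg <- walker_config(spacing = 1, q = 1e-5, n = 4000, seed = 2,
                       trap_on = FALSE, p_return = 0)
  res <- simulate_walker(cfg)
  expect_gt(res$p_transfer[["estimate"]], 0.97)
})

test_that("saturating trap eliminates the dissociative pathway", {
  cfg <- walker_config(spacing = 5, q = 0.02, n = 5000, seed = 4,
                       trap_on = TRUE, p_return = 0.9)
  res <- simulate_walker(cfg)
  expect_identical(unname(res$p_diss[["estimate"]]), 0)
  expect_equal(res$p_transfer[["estimate"]], res$p_assoc[["estimate"]])
  # every terminating molecule ended in escape, capture, or excision
  expect_true(all(res$molecules$outcome %in%
                    c("escape", "trap_capture", "excision")))
})

test_that("walker matches the first-passage oracle over a (spacing, q) grid", {
  # saturating trap isolates pure sliding, the regime the oracle describes
  for (sp in c(5, 10, 20)) {
    for (q in c(0.002, 0.005, 0.02)) {
      cfg <- walker_config(spacing = sp, q = q, n = 20000,
                           seed = 1000 + sp + round(1e4 * q))
      res <- simulate_walker(cfg)
      p_hat <- res$p_transfer[["estimate"]]
      se <- res$p_transfer[["se"]]
      p_exact <- first_passage_oracle(sp, q, left_extent = 150)
      expect_lt(abs(p_hat - p_exact), 3 * se + 1e-12)
    }
  }
})

test_that("associative transfer decays with site spacing at fixed q", {
  p <- vapply(c(5, 10, 20, 40), function(sp) {
    simulate_walker(walker_config(spacing = sp, q = 0.005, n = 15000,
                                  seed = 77))$p_transfer[["estimate"]]
  }, numeric(1))
  expect_true(all(diff(p) <= 0))
})

test_that("walker runs are reproducible and event logs are well formed", {
  cfg <- walker_config(spacing = 8, q = 0.01, n = 500, seed = 12,
                       trap_on = FALSE, p_return = 0.6)
  r1 <- simulate_walker(cfg, record_events = TRUE)
  r2 <- simulate_walker(cfg, record_events = TRUE)
  expect_identical(r1$molecules, r2$molecules)
  expect_identical(r1$events, r2$events)
  ev <- r1$events
  # terminal event of each logged molecule is escape/trap_capture/excision
  last <- ev[!duplicated(ev$molecule, fromLast = TRUE), ]
  expect_true(all(last$kind %in% c(3, 4, 5)))
  # excision events occur only at site 2 (site 1 is already excised)
  expect_true(all(ev$pos_bp[ev$kind == 5] == cfg$site2_pos))
})
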