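test_that("noiseless closed loop recovers the calibrated optimum", {
  cfg <- noiseless_config()
  res <- run_closed_loop(cfg, seed = 1)
  expect_true(res$converged)
  expect_lt(abs(res$par - 9.7), 4 * cfg$optimizer$min_step)
})

test_that("closed loop recovers a relocated response centre across the range", {
  for (ctr in seq(4, 26, by = 2)) {
    cfg <- noiseless_config(response_center = ctr)
    cfg$optimizer$guess <- 15
    cfg$optimizer$step <- 3
    res <- run_closed_loop(cfg, seed = 1)
    expect_lt(abs(res$par - ctr), 0.4)
  }
})

test_that("the simulated clock advances by transit plus window each evaluation", {
  cfg <- noiseless_config()
  res <- run_closed_loop(cfg, seed = 1)
  geom <- config_geometry(cfg)
  expected <- vapply(res$log$flowrate, function(q) {
    transit_time(geom, config_flows(cfg, q), geom$injection_junction_pos[1],
                 geom$detector_pos) + cfg$detector$window_min
  }, numeric(1))
  expect_equal(diff(c(0, res$log$clock_min)), expected, tolerance = 1e-12)
  expect_true(all(diff(res$log$clock_min) > 0))
})

test_that("run logs are complete and byte-identical under a fixed seed", {
  cfg <- default_config()
  r1 <- run_closed_loop(cfg, seed = 42)
  r2 <- run_closed_loop(cfg, seed = 42)
  expect_identical(r1$log, r2$log)
  # one log row per optimizer evaluation, evaluations strictly increasing
  expect_equal(nrow(r1$log), r1$iterations + 2)
  expect_equal(r1$log$eval, seq_len(nrow(r1$log)))
  expect_true(r1$log$converged[nrow(r1$log)])
  # a different seed gives a different noise stream
  r3 <- run_closed_loop(cfg, seed = 43)
  expect_false(identical(r1$log$mean_transmission, r3$log$mean_transmission))
})

test_that("all three characterized starts converge on budget under noise", {
  cfg <- default_config()
  starts <- list(c(5, 2), c(15, 3), c(24, 4))
  for (gs in starts) {
    cfg$optimizer$guess <- gs[1]
    cfg$optimizer$step <- gs[2]
    res <- run_closed_loop(cfg, seed = 7)
    expect_true(res$converged)
    expect_lte(res$iterations, 10)
    expect_lt(abs(res$par - 9.7), 0.5)
  }
})

test_that("replicate_study summarizes dispersion and tolerates aborts", {
  cfg <- default_config()
  rs <- replicate_study(cfg, seeds = 1:4)
  expect_equal(nrow(rs$runs), 4)
  expect_false(any(rs$runs$aborted))
  expect_equal(rs$mean, mean(rs$runs$converged_q))
  # identical seeds contribute zero dispersion between them
  rs2 <- replicate_study(cfg, seeds = c(5, 5))
  expect_equal(rs2$sd, 0)
  # noiseless replicates are deterministic up to initialization
  rs3 <- replicate_study(noiseless_config(), seeds = 1:3)
  expect_lte(rs3$sd, cfg$optimizer$min_step)
  expect_error(replicate_study(cfg, seeds = 1), "at least 2")
})
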