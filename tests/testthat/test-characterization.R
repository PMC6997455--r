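test_that("size statistics use sample moments with the n-1 denominator", {
  one <- data.frame(core_nm = 5.8, shell_nm = 3.5, total_nm = 12.8)
  s <- size_statistics(one)
  expect_equal(c(s$core_mean, s$shell_mean, s$total_mean), c(5.8, 3.5, 12.8))
  expect_equal(c(s$core_sd, s$shell_sd, s$total_sd), c(0, 0, 0))

  two <- data.frame(core_nm = c(5, 7), shell_nm = c(3, 4), total_nm = c(11, 15))
  s2 <- size_statistics(two)
  expect_equal(s2$core_sd, sqrt(((5 - 6)^2 + (7 - 6)^2) / 1))
  expect_equal(s2$n, 2)
  expect_error(size_statistics(one[0, ]), "empty")
})

test_that("statistics on generator output recover the generator parameters", {
  p <- sample_particles(5000, 9.7, seed = 9)
  s <- size_statistics(p)
  expect_lt(abs(s$core_mean - 5.8), 3 * 1.4 / sqrt(5000))
  expect_lt(abs(s$shell_mean - 3.5), 3 * 0.6 / sqrt(5000))
  expect_lt(abs(s$core_sd - 1.4), 0.1)
})

test_that("shell-vs-flowrate fit recovers the growth law", {
  q <- c(3, 6, 9, 12, 15, 18, 21)
  fit <- fit_shell_vs_flowrate(q, shell_thickness(q))
  expect_equal(fit$slope, 3.5 / 9.7, tolerance = 1e-10)
  expect_equal(fit$intercept, 0, tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)
  # two points always fit exactly
  expect_equal(fit_shell_vs_flowrate(c(2, 10), c(1, 4))$r_squared, 1)
  expect_error(fit_shell_vs_flowrate(c(5, 5), c(1, 2)), "degenerate")
})

test_that("noisy calibration pairs recover the slope within sampling error", {
  set.seed(21)
  q <- rep(c(3, 6, 9, 12, 15, 18, 21), each = 5)
  t <- shell_thickness(q) + rnorm(length(q), 0, 0.6)
  fit <- fit_shell_vs_flowrate(q, t)
  se <- 0.6 / sqrt(sum((q - mean(q))^2))
  expect_lt(abs(fit$slope - 3.5 / 9.7), 3 * se)
})

test_that("gold mass fraction follows spherical core-shell geometry", {
  expect_equal(gold_mass_fraction(5.8, 0), 0)
  # equal densities reduce to a volume ratio: 1 - (1/2)^3
  expect_equal(gold_mass_fraction(2, 1, 5, 5), 0.875)
  expect_equal(gold_mass_fraction(5.8, 3.5, 5.17, 19.3), 0.9732,
               tolerance = 1e-4)
  # monotone in shell thickness and shell density
  t <- seq(0, 5, by = 0.5)
  expect_true(all(diff(gold_mass_fraction(5.8, t)) > 0))
  expect_lt(gold_mass_fraction(5.8, 3.5, shell_density = 10),
            gold_mass_fraction(5.8, 3.5, shell_density = 19.3))
  expect_error(gold_mass_fraction(0, 1), "positive")
})

test_that("histograms are left-closed right-open and conserve counts", {
  h <- size_histogram(c(1.0, 1.5, 2.0), 1)
  expect_equal(h$count, c(2, 1))
  expect_equal(h$bin_left, c(1, 2))
  set.seed(3)
  x <- rnorm(5000, 5.8, 1.4)
  h2 <- size_histogram(x, 0.5)
  expect_equal(sum(h2$count), 5000)
  # modal bin sits at the distribution mean within one bin
  modal <- h2$bin_left[which.max(h2$count)]
  expect_lt(abs(modal - 5.8), 2 * 0.5)
  expect_error(size_histogram(numeric(0), 1), "empty")
  expect_error(size_histogram(1:3, 0), "positive")
})
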