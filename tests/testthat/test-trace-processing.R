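test_that("threshold is the 10th/90th percentile midpoint", {
  tr <- transmission_trace(rep(c(0.4, 0.9), each = 100), 50)
  expect_equal(estimate_threshold(tr), 0.65)
  # shift equivariance
  shifted <- transmission_trace(tr$intensities + 0.05, 50)
  expect_equal(estimate_threshold(shifted), 0.70)
  expect_error(estimate_threshold(transmission_trace(rep(0.9, 100), 50)),
               "degenerate")
})

test_that("segmentation finds maximal below-threshold runs", {
  x <- c(rep(0.9, 10), rep(0.3, 8), rep(0.9, 10), rep(0.3, 8), rep(0.9, 6),
         0.3, 0.3, rep(0.9, 6))  # last dip too short for min_width 3
  tr <- transmission_trace(x, 50)
  seg <- segment_droplets(tr, 0.6)
  expect_equal(nrow(seg), 2)
  expect_equal(seg$start_index, c(11, 29))
  expect_equal(seg$end_index, c(18, 36))
  expect_equal(seg$mean_intensity, c(0.3, 0.3))
  # threshold above everything: the whole trace is one run (documented edge)
  all_below <- segment_droplets(tr, 1.0)
  expect_equal(nrow(all_below), 1)
  expect_equal(all_below$n_samples, length(x))
})

test_that("segment count under default noise stays within 2% of truth", {
  cal <- calibration_model()
  counts <- vapply(1:100, function(s) {
    tr <- make_trace(9.7, cal, seed = s, duration = 2)
    nrow(segment_droplets(tr, estimate_threshold(tr)))
  }, numeric(1))
  expect_true(all(abs(counts - 120) <= 0.02 * 120))
})

test_that("droplet mean transmission summarizes segments and flags emptiness", {
  one <- data.frame(start_index = 1L, end_index = 5L, n_samples = 5L,
                    mean_intensity = 0.5)
  expect_equal(droplet_mean_transmission(one),
               list(mean = 0.5, count = 1, sd = 0))
  two <- rbind(one, data.frame(start_index = 10L, end_index = 14L,
                               n_samples = 5L, mean_intensity = 0.6))
  res <- droplet_mean_transmission(two)
  expect_equal(res$mean, 0.55)
  expect_equal(res$sd, stats::sd(c(0.5, 0.6)))
  expect_error(droplet_mean_transmission(one[0, ]), "no droplets")
})

test_that("noiseless pipeline identity: extracted mean equals the built-in value", {
  cal <- calibration_model()
  for (q in c(3, 9.7, 18)) {
    tr <- make_trace(q, cal, noise = FALSE)
    res <- extract_droplet_signal(tr)
    expect_equal(res$mean, droplet_transmission(q, cal), tolerance = 1e-12)
    expect_equal(res$sd, 0)
  }
})

test_that("extracted mean is invariant to extra baseline samples", {
  cal <- calibration_model()
  tr <- make_trace(9.7, cal, noise = FALSE)
  thr <- estimate_threshold(tr)
  padded <- transmission_trace(
    c(rep(cal$baseline_transmission, 500), tr$intensities), tr$sampling_rate)
  res <- droplet_mean_transmission(segment_droplets(padded, thr))
  expect_equal(res$mean,
               droplet_mean_transmission(segment_droplets(tr, thr))$mean,
               tolerance = 1e-12)
})
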