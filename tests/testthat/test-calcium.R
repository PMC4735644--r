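test_that("background-corrected traces subtract and normalize", {
  h <- 24
  frames <- array(20, dim = c(h, h, 10))
  roi <- disk_mask(h, h, radius = 5)
  bg <- disk_mask(h, h, center = c(3, 3), radius = 2) & !roi
  vals <- seq(100, 145, by = 5)
  for (i in 1:10) frames[, , i][roi] <- vals[i] + 20
  st <- frame_stack(frames, 100)
  tr <- extract_corrected_trace(st, roi, bg, smoothing_window = 0)
  expect_equal(tr$F_corrected, vals)
  expect_equal(min(tr$F_norm), 0)
  expect_equal(max(tr$F_norm), 1)
  expect_error(extract_corrected_trace(st, roi, roi), "overlap")
  expect_error(extract_corrected_trace(st, roi & FALSE, bg), "empty")
  # noise-free synthetic stack round-trips through extraction
  spec <- synthetic_calcium_spec(duration = 2, noise_sd = 0,
                                 background_level = 10)
  g <- gen_calcium_trace(spec, as_stack = TRUE)
  tr2 <- extract_corrected_trace(g$stack, g$roi, g$background_roi,
                                 smoothing_window = 0)
  transient <- g$trace$value - 10
  expect_equal(tr2$F_corrected / transient, rep(1, length(transient)),
               tolerance = 1e-6)
})

test_that("transient segmentation finds one window per beat", {
  flat <- as_corrected_trace(seq(0, 1, by = 0.01), rep(5, 101))
  expect_length(segment_transients(flat), 0L)
  spec <- synthetic_calcium_spec(beat_frequency = 1, tau_decay = 0.25,
                                 duration = 10, noise_sd = 0)
  mt <- make_calcium_trace(spec)
  wins <- segment_transients(mt$trace)
  expect_length(wins, 10L)
  starts <- vapply(wins, function(w) mt$trace$time_s[w$start], numeric(1))
  expect_lt(max(abs(starts - mt$truth$beat_start)), 0.03)
})

test_that("time to peak follows the 10 percent rule", {
  # linear ramp 0 -> 1 over 100 ms: crossing at 10 ms, peak at 100 ms
  t <- seq(0, 0.5, by = 0.001)
  y <- pmin(pmax((t - 0.2) / 0.1, 0), 1)
  tr <- as_corrected_trace(t, y, smoothing_samples = 1)
  w <- transient_window(1, length(t) + 1, which(y >= 1)[1], 0)
  expect_lte(abs(as.numeric(time_to_peak(w, tr)) - 0.09), 0.001 + 1e-9)
  # one-sample rise is degenerate
  y2 <- c(rep(0, 10), rep(1, 10))
  tr2 <- as_corrected_trace(seq(0, 1.9, by = 0.1), y2, smoothing_samples = 1)
  w2 <- transient_window(1, 21, 11, 0)
  ttp2 <- time_to_peak(w2, tr2)
  expect_true(isTRUE(attr(ttp2, "degenerate")) || as.numeric(ttp2) <= 0.1)
  # synthetic transient: within one frame interval of the analytic truth
  # (unsmoothed: a 50 ms rise spans only 5 samples at 100 frames/s, so
  # the default moving average would distort the rise itself)
  spec <- synthetic_calcium_spec(rise_time = 0.05, duration = 3, noise_sd = 0)
  mt <- make_calcium_trace(spec, smoothing_samples = 1)
  m <- transient_metrics(mt$trace)
  expect_lt(max(abs(m$time_to_peak_s - mt$truth$time_to_peak)), 0.011)
})

test_that("FWHM identities hold to one sample interval", {
  dt <- 0.001
  t <- seq(0, 1, by = dt)
  # symmetric triangle of base width 0.2: FWHM = 0.1
  y <- pmax(0, 1 - abs(t - 0.5) / 0.1)
  tr <- as_corrected_trace(t, y, smoothing_samples = 1)
  w <- transient_window(1, length(t) + 1, which.max(y), 0)
  expect_lte(abs(fwhm(w, tr) - 0.1), dt)
  # instantaneous rise then exponential: FWHM = tau ln 2
  tau <- 0.3
  y2 <- ifelse(t < 0.1, 0, exp(-(t - 0.1) / tau))
  tr2 <- as_corrected_trace(t, y2, smoothing_samples = 1)
  w2 <- transient_window(1, length(t) + 1, which.max(y2), 0)
  expect_lte(abs(fwhm(w2, tr2) - tau * log(2)), dt)
  # downstroke never reaching half maximum is flagged
  y3 <- pmin((t) / 0.2, 1)
  tr3 <- as_corrected_trace(t, y3, smoothing_samples = 1)
  w3 <- transient_window(1, length(t) + 1, which(y3 >= 1)[1], 0)
  expect_true(is.na(fwhm(w3, tr3)))
  # synthetic transient FWHM within 1.5 frame intervals of analytic
  # truth; 0.5 Hz beats let each decay resolve fully before the next
  spec <- synthetic_calcium_spec(beat_frequency = 0.5, duration = 6,
                                 noise_sd = 0)
  mt <- make_calcium_trace(spec, smoothing_samples = 1)
  m <- transient_metrics(mt$trace)
  expect_lt(max(abs(m$fwhm_s - mt$truth$fwhm)), 1.5 / 100)
})

test_that("decay fitting recovers tau and flags degenerate input", {
  # pure exponential, no noise
  spec <- synthetic_calcium_spec(tau_decay = 0.3, beat_frequency = 0.5,
                                 duration = 2, noise_sd = 0)
  mt <- make_calcium_trace(spec, smoothing_samples = 1)
  m <- transient_metrics(mt$trace)
  expect_equal(m$tau_s[1], 0.3, tolerance = 0.01)
  expect_gt(m$r_squared[1], 0.999)
  # constant segment does not converge
  tr <- as_corrected_trace(seq(0, 1, by = 0.01), rep(3, 101),
                           smoothing_samples = 1)
  w <- transient_window(1, 102, 1, 3)
  fit <- fit_decay_tau(w, tr)
  expect_false(fit$converged)
  # monotonicity: larger generator tau gives larger fitted tau and FWHM
  taus <- c(0.15, 0.25, 0.35)
  out <- vapply(taus, function(tau) {
    spec <- synthetic_calcium_spec(tau_decay = tau, beat_frequency = 0.5,
                                   duration = 2, noise_sd = 0)
    m <- transient_metrics(make_calcium_trace(spec)$trace)
    c(m$tau_s[1], m$fwhm_s[1])
  }, numeric(2))
  expect_true(all(diff(out[1, ]) > 0))
  expect_true(all(diff(out[2, ]) > 0))
})

test_that("metrics are invariant under affine intensity rescaling", {
  spec <- synthetic_calcium_spec(duration = 3, noise_sd = 1, seed = 8)
  g <- gen_calcium_trace(spec)
  tr1 <- as_corrected_trace(g$trace$time_s, g$trace$value)
  tr2 <- as_corrected_trace(g$trace$time_s, 3.7 * g$trace$value + 250)
  m1 <- transient_metrics(tr1)
  m2 <- transient_metrics(tr2)
  expect_equal(m1$time_to_peak_s, m2$time_to_peak_s, tolerance = 1e-8)
  expect_equal(m1$fwhm_s, m2$fwhm_s, tolerance = 1e-8)
  expect_equal(m1$tau_s, m2$tau_s, tolerance = 1e-6)
})
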