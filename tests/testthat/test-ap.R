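test_that("AP detection counts upstrokes and honours the refractory rule", {
  # flat trace: no events
  flat <- voltage_trace(seq(0, 1, by = 1e-4), rep(-60, 10001))
  expect_identical(nrow(detect_aps(flat)), 0L)
  # 1 Hz train of 5 beats: 5 events near the true upstroke times
  g <- gen_ap_trace(synthetic_ap_spec("ventricular_like", n_beats = 5,
                                      noise_sd = 0, seed = 2))
  tr <- voltage_trace(g$trace$time_s, g$trace$voltage_mV)
  ev <- detect_aps(tr)
  expect_identical(nrow(ev), 5L)
  t_up <- (ev$upstroke - 1) / g$sampling_rate
  expect_lt(max(abs(t_up - g$truth$upstroke_times)), 0.01)
  # events closer than min_cycle are merged
  fs <- 10000
  t <- seq(0, 0.6, by = 1 / fs)
  v <- rep(-60, length(t))
  mk_spike <- function(v, t0) {
    i <- round(t0 * fs)
    v[i:(i + 20)] <- -60 + (0:20) * 4.5   # ~45 mV/ms upstroke
    v[(i + 21):(i + 60)] <- seq(30, -60, length.out = 40)
    v
  }
  v <- mk_spike(v, 0.2)
  v <- mk_spike(v, 0.25)
  ev2 <- detect_aps(voltage_trace(t, v), min_cycle = 0.2)
  expect_identical(nrow(ev2), 1L)
})

test_that("per-AP features recover the generator ground truth", {
  g <- gen_ap_trace(synthetic_ap_spec("ventricular_like", n_beats = 3,
                                      noise_sd = 0, seed = 3))
  tr <- voltage_trace(g$trace$time_s, g$trace$voltage_mV)
  res <- analyze_ap_trace(tr)
  m <- res$metrics
  tru <- g$truth
  expect_equal(stats::median(m$mdp), tru$mdp, tolerance = 0.01)
  expect_equal(stats::median(m$peak_amplitude), tru$peak_amplitude,
               tolerance = 0.01)
  expect_equal(stats::median(m$dvdt_max), tru$dvdt_max, tolerance = 0.02)
  expect_equal(stats::median(m$apd90), tru$apd90, tolerance = 0.002)
  expect_equal(stats::median(m$apd30), tru$apd30, tolerance = 0.005)
  expect_true(all(m$apd30 <= m$apd50 & m$apd50 <= m$apd90))
  expect_equal(stats::median(m$phase4_slope), tru$phase4_slope,
               tolerance = 0.02)
  expect_equal(res$rate$rate, tru$rate, tolerance = 0.01)
})

test_that("a sawtooth with known constant slope gives that dvdt_max", {
  fs <- 10000
  t <- seq(0, 1, by = 1 / fs)
  v <- rep(-60, length(t))
  # linear upstroke at exactly 50 mV/ms over 2 ms, then linear decay
  i0 <- 5001
  v[i0:(i0 + 19)] <- -60 + 5 * (1:20)
  v[(i0 + 20):(i0 + 419)] <- seq(40, -60, length.out = 400)
  tr <- voltage_trace(t, v)
  ev <- detect_aps(tr)
  expect_identical(nrow(ev), 1L)
  m <- ap_metrics(tr, ev[1, ])
  expect_equal(m$dvdt_max, 50, tolerance = 0.02)
})

test_that("voltage offsets shift potentials but not durations or slopes", {
  g <- gen_ap_trace(synthetic_ap_spec("rapid_depolarizer", n_beats = 3,
                                      noise_sd = 0.2, seed = 4))
  tr1 <- voltage_trace(g$trace$time_s, g$trace$voltage_mV)
  tr2 <- voltage_trace(g$trace$time_s, g$trace$voltage_mV + 17)
  m1 <- analyze_ap_trace(tr1)$metrics
  m2 <- analyze_ap_trace(tr2)$metrics
  expect_equal(m2$mdp, m1$mdp + 17, tolerance = 1e-9)
  expect_equal(m2$peak_voltage, m1$peak_voltage + 17, tolerance = 1e-9)
  expect_equal(m2$take_off_potential, m1$take_off_potential + 17,
               tolerance = 1e-9)
  expect_equal(m2$peak_amplitude, m1$peak_amplitude, tolerance = 1e-9)
  expect_equal(m2$dvdt_max, m1$dvdt_max, tolerance = 1e-9)
  expect_equal(m2$apd90, m1$apd90, tolerance = 1e-9)
})

test_that("time rescaling from 10 to 5 kHz barely moves APD90 and dvdt", {
  g10 <- gen_ap_trace(synthetic_ap_spec("ventricular_like", n_beats = 3,
                                        sampling_rate = 10000,
                                        noise_sd = 0, seed = 6))
  g5 <- gen_ap_trace(synthetic_ap_spec("ventricular_like", n_beats = 3,
                                       sampling_rate = 5000,
                                       noise_sd = 0, seed = 6))
  m10 <- analyze_ap_trace(voltage_trace(g10$trace$time_s,
                                        g10$trace$voltage_mV))$metrics
  m5 <- analyze_ap_trace(voltage_trace(g5$trace$time_s,
                                       g5$trace$voltage_mV))$metrics
  expect_lt(abs(stats::median(m10$apd90) - stats::median(m5$apd90)), 1)
  expect_lt(abs(stats::median(m10$dvdt_max) - stats::median(m5$dvdt_max)) /
              stats::median(m10$dvdt_max), 0.05)
})

test_that("spontaneous rate reports both estimators", {
  ev <- data.frame(upstroke = c(1, 10001, 20001, 30001, 40001),
                   peak = c(100, 10100, 20100, 30100, 40100),
                   mdp_before = c(1, 9000, 19000, 29000, 39000),
                   mdp_after = c(9000, 19000, 29000, 39000, 49000))
  r <- spontaneous_rate(ev, duration = 5, sampling_rate = 10000)
  expect_equal(r$rate, 1)
  expect_equal(r$rate_interval, 1)
  r0 <- spontaneous_rate(ev[0, ], duration = 5, sampling_rate = 10000)
  expect_equal(r0$rate, 0)
  expect_true(is.na(r0$rate_interval))
})

test_that("Tukey fence matches a brute-force oracle and flags plants", {
  # oracle equivalence over 1,000 random cohorts
  set.seed(42)
  agree <- vapply(seq_len(1000), function(i) {
    n <- sample(4:40, 1)
    v <- stats::rnorm(n, 24, 3)
    if (stats::runif(1) < 0.5) v <- c(v, stats::runif(2, 40, 120))
    identical(classify_rapid_depolarizers(v)$flags, brute_force_tukey(v))
  }, logical(1))
  expect_true(all(agree))
  # planted-outlier cohort: exactly the plant is flagged
  coh <- gen_cohort(20, 24, 3, outlier_values = 88, seed = 1)
  cls <- classify_rapid_depolarizers(coh$cohort$dvdt_max)
  expect_identical(cls$flags, coh$cohort$planted_outlier)
  expect_equal(cls$cutoff, cls$q3 + 1.5 * cls$iqr)
  # degenerate all-equal cohort: iqr 0, nothing flagged
  cls0 <- classify_rapid_depolarizers(rep(24, 8))
  expect_equal(cls0$iqr, 0)
  expect_false(any(cls0$flags))
  # no outliers by construction
  expect_false(any(classify_rapid_depolarizers(c(10, 11, 12, 13))$flags))
  expect_error(classify_rapid_depolarizers(c(1, 2, 3)), "too small")
})

test_that("cohort summaries report group means and rapid fractions", {
  coh <- rbind(
    data.frame(dvdt_max = stats::rnorm(12, 24, 2), group = "control"),
    data.frame(dvdt_max = c(stats::rnorm(6, 24, 2), rep(85, 4)),
               group = "hz2"))
  res <- cohort_summary(coh["dvdt_max"], coh$group)
  expect_equal(unname(res$fraction_rapid["control"]), 0)
  expect_equal(unname(res$fraction_rapid["hz2"]), 0.4)
  s <- res$summary
  expect_true(all(c("control", "hz2") %in% s$group))
  # single-cell group: mean = value, sem absent
  one <- data.frame(dvdt_max = c(20, 21, 22, 23, 50))
  res1 <- cohort_summary(one, c("a", "a", "a", "a", "b"))
  sb <- res1$summary[res1$summary$group == "b", ]
  expect_equal(sb$mean, 50)
  expect_true(is.na(sb$sem))
  expect_error(cohort_summary(one, c("a", "a", "a", "a")), "one group label")
})
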