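test_that("beat waveform is periodic, normalized and amplitude-independent", {
  spec <- beat_waveform_spec(1, duty_fraction = 0.3, amplitude = 0.2)
  t <- seq(0, 10, by = 0.01)
  s <- gen_beat_waveform(spec, t)
  expect_true(all(s >= 0 & s <= 1))
  # one maximum per period: count strict local maxima
  n <- length(s)
  n_max <- sum(s[2:(n - 1)] > s[1:(n - 2)] & s[2:(n - 1)] > s[3:n])
  expect_identical(n_max, 10L)
  # zero between pulses
  expect_true(all(s[(t %% 1) >= 0.3] == 0))
  # amplitude does not enter s(t)
  spec2 <- beat_waveform_spec(1, duty_fraction = 0.3, amplitude = 0.7)
  expect_identical(s, gen_beat_waveform(spec2, t))
  # periodicity via brute-force autocorrelation at 2 Hz: first off-zero
  # peak of the acf sits at lag 0.5 s
  s2 <- gen_beat_waveform(beat_waveform_spec(2), seq(0, 5, by = 0.01))
  ac <- stats::acf(s2, lag.max = 120, plot = FALSE)$acf[, 1, 1]
  n2 <- length(ac)
  peaks <- which(ac[2:(n2 - 1)] > ac[1:(n2 - 2)] & ac[2:(n2 - 1)] > ac[3:n2]) + 1L
  expect_equal((peaks[1] - 1) * 0.01, 0.5, tolerance = 0.03)
  expect_error(beat_waveform_spec(-1), "positive")
})

test_that("contraction video: geometry, determinism, intensity scaling", {
  # frame rate 20 samples the pulse maximum exactly (peak at t = 0.15 s)
  gv <- make_video(amplitude = 0.1, duration = 2, frame_rate = 20,
                   noise_sd = 0)
  tru <- gv$truth$foci[[1]]
  # disk area scales with the squared radius
  expect_lt(abs(min(tru$area) / max(tru$area) - 0.81), 1e-10)
  # (near-)zero amplitude and no noise: all frames identical
  gv0 <- gen_contraction_video(synthetic_video_spec(
    beat_waveform_spec(1, amplitude = 1e-9), duration = 1, noise_sd = 0))
  f <- gv0$stack$frames
  expect_lt(max(abs(sweep(f, c(1, 2), f[, , 1]))), 1e-7)
  # determinism under a fixed seed
  gv2 <- make_video(amplitude = 0.1, duration = 2, frame_rate = 20,
                    noise_sd = 0)
  expect_identical(gv$stack$frames, gv2$stack$frames)
  # overlapping foci rejected
  expect_error(synthetic_video_spec(
    list(beat_waveform_spec(1), beat_waveform_spec(2)),
    centers = rbind(c(32, 30), c(32, 34)), base_radius = c(10, 10)),
    "overlap")
})

test_that("speckle pairs carry exactly the requested shift", {
  sp0 <- gen_speckle_pair(c(0, 0), seed = 4)
  expect_equal(sp0$frame_a, sp0$frame_b, tolerance = 1e-12)
  # integer shift: brute-force full-image correlation peaks at the shift
  sp <- gen_speckle_pair(c(3, -2), seed = 4)
  h <- nrow(sp$frame_a)
  A <- sp$frame_a - mean(sp$frame_a)
  B <- sp$frame_b - mean(sp$frame_b)
  cc <- Re(stats::fft(Conj(stats::fft(A)) * stats::fft(B), inverse = TRUE))
  pk <- arrayInd(which.max(cc), dim(cc))
  lag <- function(i) ifelse(i - 1 > h / 2, i - 1 - h, i - 1)
  expect_equal(c(lag(pk[1]), lag(pk[2])), c(-2, 3))  # (row, col) = (dy, dx)
  # half-pixel shift: correlation at lags 0 and 1 nearly equal
  sph <- gen_speckle_pair(c(0.5, 0), seed = 4)
  A <- sph$frame_a - mean(sph$frame_a)
  B <- sph$frame_b - mean(sph$frame_b)
  cc <- Re(stats::fft(Conj(stats::fft(A)) * stats::fft(B), inverse = TRUE))
  expect_equal(cc[1, 2] / cc[1, 1], 1, tolerance = 0.1)
  expect_error(gen_speckle_pair(c(40, 0)), "quarter")
})

test_that("calcium generator matches its analytic ground truth", {
  spec <- synthetic_calcium_spec(beat_frequency = 1, tau_decay = 0.25,
                                 rise_time = 0.05, duration = 3,
                                 frame_rate = 100, noise_sd = 0)
  g <- gen_calcium_trace(spec)
  # log-linear decay from the first peak with slope -1/tau
  i_pk <- which.max(g$trace$value[1:100])
  seg <- i_pk:(i_pk + 50)
  y <- log(g$trace$value[seg] - 100)   # baseline = 100
  fit <- stats::lm(y ~ g$trace$time_s[seg])
  expect_equal(unname(stats::coef(fit)[2]), -4, tolerance = 0.01)
  # peak value = baseline * (1 + peak_dF)
  expect_equal(max(g$trace$value), 200, tolerance = 1e-6)
  # unresolvable transients rejected
  expect_error(synthetic_calcium_spec(beat_frequency = 2, tau_decay = 0.3),
               "unresolvable")
})

test_that("AP generator reproduces requested morphology exactly", {
  g <- gen_ap_trace(synthetic_ap_spec("ventricular_like", n_beats = 3,
                                      noise_sd = 0, seed = 1))
  v <- g$trace$voltage_mV
  expect_equal(min(v), -60, tolerance = 1e-6)
  expect_equal(max(v), 30, tolerance = 1e-3)
  # requested dvdt_max appears in the finite differences (within 2%)
  raw_max <- max(diff(v)) * g$sampling_rate / 1000
  expect_equal(raw_max, 24, tolerance = 0.02)
  g88 <- gen_ap_trace(synthetic_ap_spec("rapid_depolarizer", n_beats = 2,
                                        noise_sd = 0, seed = 1))
  raw88 <- max(diff(g88$trace$voltage_mV)) * g88$sampling_rate / 1000
  expect_equal(raw88, 88, tolerance = 0.02)
  # exactly n_beats upstrokes
  expect_length(g$truth$upstroke_times, 3L)
  # infeasible morphologies rejected
  expect_error(synthetic_ap_spec(apd30 = 300, apd50 = 250), "apd30 < apd50")
  expect_error(synthetic_ap_spec("rapid_depolarizer", rate = 8), "cycle length")
})

test_that("cohort and Ct-table generators are deterministic with truth", {
  c1 <- gen_cohort(10, outlier_values = numeric(), seed = 2)
  expect_false(any(c1$cohort$planted_outlier))
  c2 <- gen_cohort(10, outlier_values = numeric(), seed = 2)
  expect_identical(c1$cohort, c2$cohort)
  c3 <- gen_cohort(20, 24, 3, outlier_values = 88, seed = 1)
  expect_identical(which(c3$cohort$planted_outlier), 21L)
  expect_error(gen_cohort(3), "at least 4")

  g <- gen_ct_table("KCNH2", c("ctrl", "stim"), true_fold_changes = 2,
                    seed = 1)
  tab <- g$table
  ct_ctrl <- tab$ct[tab$gene == "KCNH2" & tab$group == "ctrl"]
  ct_stim <- tab$ct[tab$gene == "KCNH2" & tab$group == "stim"]
  expect_equal(unique(ct_ctrl - 20), 0)
  expect_equal(unique(ct_stim - 20), -1)   # fold 2 = one cycle earlier
})

test_that("frame stacks round-trip through multipage TIFF", {
  gv <- make_video(duration = 0.2, frame_rate = 20, noise_sd = 0.01)
  path <- tempfile(fileext = ".tif")
  write_frame_stack(gv$stack, path)
  rt <- read_frame_stack(path, frame_rate = 20)
  expect_equal(dim(rt$frames), dim(gv$stack$frames))
  expect_equal(rt$frames, gv$stack$frames, tolerance = 1 / 65535 * 2)
  unlink(path)
})
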