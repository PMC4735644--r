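test_that("strain rate matches closed forms on analytic fields", {
  gx <- seq(8, 120, by = 8)
  gy <- gx
  dt <- 1 / 30
  k <- 0.05
  u <- -k * outer(rep(1, length(gy)), gx)
  v <- -k * outer(gy, rep(1, length(gx)))
  sr <- velocity_to_strain_rate(velocity_field(gx, gy, u, v), dt)
  expect_equal(max(abs(sr$scalar - 2 * k / dt)) / (2 * k / dt), 0,
               tolerance = 1e-6)
  # uniform translation: exactly zero
  n <- length(gx)
  sr0 <- velocity_to_strain_rate(
    velocity_field(gx, gy, matrix(3, n, n), matrix(-2, n, n)), dt)
  expect_equal(max(abs(sr0$scalar)), 0)
  # divergence sign convention is switchable
  srd <- velocity_to_strain_rate(velocity_field(gx, gy, u, v), dt,
                                 sign_convention = "divergence")
  expect_equal(srd$scalar, -sr$scalar)
  expect_error(velocity_to_strain_rate(
    velocity_field(gx[1], gy[1], matrix(0), matrix(0)), dt), "degenerate")
})

test_that("strain traces average over the masked area", {
  gx <- seq(8, 56, by = 8)
  n <- length(gx)
  mk_field <- function(c_val) {
    f <- velocity_to_strain_rate(
      velocity_field(gx, gx, matrix(0, n, n), matrix(0, n, n)), 1)
    f$scalar[] <- c_val
    f
  }
  tr <- strain_trace(list(mk_field(0.2), mk_field(-0.1)), 1 / 30)
  expect_equal(tr$mean_strain_rate, c(0.2, -0.1))
  expect_length(tr$time_s, 2L)
  mask <- matrix(FALSE, 64, 64)
  expect_error(strain_trace(list(mk_field(1)), 1 / 30, mask = mask),
               "excludes")
})

test_that("cumulative strain integrates positive rates only", {
  # rectangular positive pulse: height 0.2/s, width 0.5 s, one beat
  dt <- 0.05
  rate <- c(rep(0, 10), rep(0.2, 10), rep(0, 10))
  tr <- structure(data.frame(time_s = (seq_along(rate) - 0.5) * dt,
                             mean_strain_rate = rate),
                  class = c("strain_trace", "data.frame"))
  attr(tr, "frame_interval") <- dt
  cm <- contraction_metrics(tr, n_beats = 1)
  expect_equal(cm$cumulative_strain, 0.1)
  expect_equal(cm$strain_per_beat, 0.1)
  # all-negative trace integrates to zero; per-beat NA with no beats
  tr$mean_strain_rate <- -abs(tr$mean_strain_rate)
  cm0 <- contraction_metrics(tr, n_beats = 0)
  expect_equal(cm0$cumulative_strain, 0)
  expect_true(is.na(cm0$strain_per_beat))
})

test_that("PIV strain on a synthetic contraction matches the analytic field", {
  spec <- synthetic_video_spec(beat_waveform_spec(1, amplitude = 0.15),
                               duration = 1.2, frame_rate = 30,
                               image_size = c(96, 96), noise_sd = 0.02,
                               seed = 3)
  gv <- gen_contraction_video(spec)
  tru <- gv$truth$foci[[1]]
  pair <- which.max(abs(tru$mean_divergence))
  plan <- interrogation_plan(c(32, 16))
  vf <- compute_displacement(gv$stack$frames[, , pair],
                             gv$stack$frames[, , pair + 1], plan)
  sr <- velocity_to_strain_rate(vf, 1 / 30)
  # average over windows fully supported by object texture: erode the
  # rest mask by half the final interrogation window
  mask <- disk_mask(96, 96, radius = min(tru$radius) - 10)
  st <- strain_trace(list(sr), 1 / 30, mask = mask)
  truth_sr <- -tru$mean_divergence[pair] * 30
  expect_equal(st$mean_strain_rate, truth_sr, tolerance = 0.15)
})

test_that("contraction metrics survive 2x temporal upsampling", {
  run <- function(fr) {
    spec <- synthetic_video_spec(beat_waveform_spec(1, amplitude = 0.12),
                                 duration = 2, frame_rate = fr,
                                 image_size = c(96, 96), noise_sd = 0.01,
                                 seed = 9)
    gv <- gen_contraction_video(spec)
    plan <- interrogation_plan(c(32, 16))
    fields <- piv_stack(gv$stack, plan)
    srs <- lapply(fields, velocity_to_strain_rate, frame_interval = 1 / fr)
    mask <- disk_mask(96, 96,
                      radius = min(gv$truth$foci[[1]]$radius) - 10)
    tr <- strain_trace(srs, 1 / fr, mask = mask)
    contraction_metrics(tr, n_beats = 2)$cumulative_strain
  }
  c30 <- run(30)
  c60 <- run(60)
  expect_equal(c60 / c30, 1, tolerance = 0.1)
})

test_that("velocity heat maps clip to fixed colour limits", {
  gx <- seq(8, 56, by = 8)
  n <- length(gx)
  f0 <- velocity_field(gx, gx, matrix(0, n, n), matrix(0, n, n))
  hm0 <- render_velocity_heatmap(f0, pixel_size = 1, frame_interval = 1 / 30)
  expect_true(all(hm0$speed == 0))
  expect_equal(hm0$clip_fraction, 0)
  # 28 um/s everywhere: top colour, full clip fraction
  f28 <- velocity_field(gx, gx, matrix(28 / 30, n, n), matrix(0, n, n))
  hm28 <- render_velocity_heatmap(f28, pixel_size = 1, frame_interval = 1 / 30)
  expect_true(all(abs(hm28$speed - 28) < 1e-9))
  expect_equal(hm28$clip_fraction, 1)
  # 56 um/s clips to 28 and reports it
  f56 <- velocity_field(gx, gx, matrix(56 / 30, n, n), matrix(0, n, n))
  hm56 <- render_velocity_heatmap(f56, pixel_size = 1, frame_interval = 1 / 30)
  expect_true(all(abs(hm56$speed - 28) < 1e-9))
  expect_equal(hm56$clip_fraction, 1)
  expect_error(render_velocity_heatmap(f0, pixel_size = NULL,
                                       frame_interval = NULL), "units")
})
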