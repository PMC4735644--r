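# Synthetic contracting-object videos and speckle fixtures with full
# ground truth. These emulate bright-field recordings of beating embryoid
# bodies: a textured disk whose radius contracts periodically, so that
# every downstream estimate (area, frequency, displacement field, strain)
# can be checked against an analytic truth.

#' Specify a periodic contraction waveform
#'
#' The waveform s(t) is a dimensionless activation in \[0, 1\]: 0 at rest,
#' 1 at peak contraction. Each period contains one pulse occupying
#' `duty_fraction` of the cycle; the rest of the cycle is exactly 0.
#'
#' @param frequency beating frequency in Hz (> 0).
#' @param duty_fraction fraction of the period occupied by the pulse,
#'   in (0, 1).
#' @param amplitude peak fractional linear contraction in (0, 1); not
#'   used by the waveform itself (s is normalized to max 1) but carried
#'   for the video generator.
#' @param waveform_shape `"raised_cosine"` (symmetric pulse) or
#'   `"asymmetric"` (fast rise over 30% of the pulse, slow relaxation).
#' @return a `beat_waveform_spec` list.
#' @export
beat_waveform_spec <- function(frequency, duty_fraction = 0.3,
                               amplitude = 0.1,
                               waveform_shape = c("raised_cosine", "asymmetric")) {
  waveform_shape <- match.arg(waveform_shape)
  if (!is.numeric(frequency) || frequency <= 0)
    stop("`frequency` must be positive")
  if (duty_fraction <= 0 || duty_fraction >= 1)
    stop("`duty_fraction` must be in (0, 1)")
  if (amplitude <= 0 || amplitude >= 1)
    stop("`amplitude` must be in (0, 1)")
  structure(list(frequency = frequency, duty_fraction = duty_fraction,
                 amplitude = amplitude, waveform_shape = waveform_shape),
            class = "beat_waveform_spec")
}

#' Evaluate a contraction waveform on a time grid
#'
#' @param spec a [beat_waveform_spec()].
#' @param t_grid strictly increasing time vector (s).
#' @return numeric vector s(t) in \[0, 1\], periodic with period
#'   `1/frequency`, with max 1 within each full period and 0 between
#'   pulses.
#' @export
gen_beat_waveform <- function(spec, t_grid) {
  stopifnot(inherits(spec, "beat_waveform_spec"))
  if (any(diff(t_grid) <= 0)) stop("`t_grid` must be strictly increasing")
  phase <- (t_grid * spec$frequency) %% 1
  d <- spec$duty_fraction
  s <- numeric(length(t_grid))
  inp <- phase < d
  p <- phase[inp] / d            # pulse-local coordinate in [0, 1)
  if (spec$waveform_shape == "raised_cosine") {
    s[inp] <- 0.5 * (1 - cos(2 * pi * p))
  } else {
    rise <- 0.3
    up <- p < rise
    sp <- numeric(length(p))
    sp[up] <- 0.5 * (1 - cos(pi * p[up] / rise))
    sp[!up] <- 0.5 * (1 + cos(pi * (p[!up] - rise) / (1 - rise)))
    s[inp] <- sp
  }
  s
}

# Smoothed random speckle texture in [0, 1], used as the material pattern
# that PIV tracks. Gaussian smoothing of white noise with sd ~1 px gives
# speckles of 2-4 px, well matched to 16-px interrogation windows.
speckle_texture <- function(h, w, smooth_sd = 1.0) {
  x <- matrix(stats::rnorm(h * w), h, w)
  x <- gaussian_blur(x, smooth_sd)
  rng <- range(x)
  (x - rng[1]) / (rng[2] - rng[1])
}

# Separable Gaussian blur with reflected edges.
gaussian_blur <- function(m, sd) {
  if (sd <= 0) return(m)
  r <- max(1L, ceiling(3 * sd))
  k <- stats::dnorm(-r:r, sd = sd)
  k <- k / sum(k)
  conv1 <- function(v) {
    n <- length(v)
    vp <- c(rev(v[seq_len(r)]), v, rev(v[n - seq_len(r) + 1L]))
    stats::filter(vp, k, sides = 2)[(r + 1L):(r + n)]
  }
  m <- apply(m, 2, conv1)
  t(apply(t(m), 2, conv1))
}

# Subpixel periodic shift via Fourier phase ramp. shift = c(dx, dy) with
# dx = column displacement, dy = row displacement: the shifted image has
# the original content moved by +shift.
fourier_shift <- function(m, shift) {
  h <- nrow(m); w <- ncol(m)
  fy <- c(0:floor((h - 1) / 2), -(ceiling((h - 1) / 2):1)) / h
  fx <- c(0:floor((w - 1) / 2), -(ceiling((w - 1) / 2):1)) / w
  ph <- exp(-2i * pi * (outer(fy, rep(1, w)) * shift[2] +
                          outer(rep(1, h), fx) * shift[1]))
  Re(stats::fft(stats::fft(m) * ph, inverse = TRUE)) / (h * w)
}

#' Specify a synthetic contraction video
#'
#' One or two bright speckled disks ("foci") on a dark background, each
#' contracting radially according to its own beat waveform. A material
#' point at rest radius r sits at radius `r * (1 - amplitude * s(t))`, so
#' the segmented area, the frame-pair displacement field and its
#' divergence all have closed forms recorded in the ground truth.
#'
#' @param beats a [beat_waveform_spec()] or list of one or two of them
#'   (one per focus).
#' @param duration recording length in s.
#' @param frame_rate frames per second.
#' @param image_size c(height, width) in px.
#' @param centers matrix (one row per focus) of c(row, col) centres in
#'   px; default centres a single focus, or splits the field for two.
#' @param base_radius rest radius per focus in px.
#' @param noise_sd additive Gaussian intensity noise (frame intensities
#'   are in \[0, 1\]; foreground-background contrast is 0.5, so
#'   `noise_sd = 0.05` corresponds to SNR 10).
#' @param drift rigid drift of all foci in px/s (applied along +x).
#' @param seed integer seed; fixed seed gives bit-identical stacks.
#' @return a `synthetic_video_spec` list.
#' @export
synthetic_video_spec <- function(beats, duration = 10, frame_rate = 30,
                                 image_size = c(64, 64), centers = NULL,
                                 base_radius = NULL, noise_sd = 0.02,
                                 drift = 0, seed = 1) {
  if (inherits(beats, "beat_waveform_spec")) beats <- list(beats)
  if (!length(beats) %in% 1:2)
    stop("one or two beating foci are supported")
  if (duration * frame_rate < 2) stop("need at least 2 frames")
  n_foci <- length(beats)
  if (is.null(centers)) {
    centers <- if (n_foci == 1L) {
      matrix((image_size + 1) / 2, 1)
    } else {
      rbind(c((image_size[1] + 1) / 2, image_size[2] * 0.27),
            c((image_size[1] + 1) / 2, image_size[2] * 0.73))
    }
  }
  centers <- matrix(centers, ncol = 2)
  if (is.null(base_radius))
    base_radius <- rep(min(image_size) * (if (n_foci == 1L) 0.33 else 0.18),
                       n_foci)
  base_radius <- rep_len(base_radius, n_foci)
  if (n_foci == 2L) {
    gap <- sqrt(sum((centers[1, ] - centers[2, ])^2))
    if (gap < sum(base_radius) + 2)
      stop("foci overlap at rest; move centres apart or shrink radii")
  }
  structure(list(beats = beats, duration = duration, frame_rate = frame_rate,
                 image_size = image_size, centers = centers,
                 base_radius = base_radius, noise_sd = noise_sd,
                 drift = drift, seed = seed),
            class = "synthetic_video_spec")
}

#' Generate a synthetic contraction video
#'
#' Renders the spec into a [frame_stack()] plus a ground-truth record.
#' The speckle texture is generated once at rest and advected through the
#' radial contraction map by bilinear interpolation, so the displacement
#' field recoverable by frame-pair PIV equals the recorded truth. Truth
#' velocities are frame-to-frame position differences of material points
#' (what PIV observes), not instantaneous derivatives.
#'
#' @param spec a [synthetic_video_spec()].
#' @return list with elements `stack` (a [frame_stack()]) and `truth`, a
#'   list containing per focus: the input parameters, per-frame scale
#'   factor `lambda` (radius / rest radius), radius and disk area (px^2),
#'   and per-frame-pair mean divergence of the displacement field
#'   (px/px/frame, equal to `2 * (lambda[t+1]/lambda[t] - 1)`).
#' @export
gen_contraction_video <- function(spec) {
  stopifnot(inherits(spec, "synthetic_video_spec"))
  with_seed(spec$seed, {
    h <- spec$image_size[1]; w <- spec$image_size[2]
    n_t <- round(spec$duration * spec$frame_rate)
    t_grid <- (seq_len(n_t) - 1) / spec$frame_rate
    n_foci <- length(spec$beats)

    textures <- lapply(seq_len(n_foci), function(i) speckle_texture(h, w))
    s_list <- lapply(spec$beats, gen_beat_waveform, t_grid = t_grid)
    lambda <- lapply(seq_len(n_foci), function(i)
      1 - spec$beats[[i]]$amplitude * s_list[[i]])

    rows <- matrix(seq_len(h), h, w)
    cols <- matrix(seq_len(w), h, w, byrow = TRUE)
    bg <- 0.05
    frames <- array(bg, dim = c(h, w, n_t))
    for (ti in seq_len(n_t)) {
      img <- matrix(bg, h, w)
      dx_drift <- spec$drift * t_grid[ti]
      for (fi in seq_len(n_foci)) {
        ctr <- spec$centers[fi, ] + c(0, dx_drift)
        lam <- lambda[[fi]][ti]
        dr <- rows - ctr[1]; dc <- cols - ctr[2]
        rho <- sqrt(dr^2 + dc^2)
        inside <- rho <= spec$base_radius[fi] * lam
        if (!any(inside)) next
        # inverse map: pixel at radius rho came from rest radius rho/lam
        src_r <- spec$centers[fi, 1] + dr[inside] / lam
        src_c <- spec$centers[fi, 2] + dc[inside] / lam
        tex <- bilinear_sample(textures[[fi]], src_r, src_c, fill = 0.5)
        img[inside] <- 0.5 + 0.45 * tex
      }
      if (spec$noise_sd > 0)
        img <- img + matrix(stats::rnorm(h * w, sd = spec$noise_sd), h, w)
      img[img < 0] <- 0
      img[img > 1] <- 1
      frames[, , ti] <- img
    }

    truth <- list(
      seed = spec$seed,
      frame_rate = spec$frame_rate,
      n_frames = n_t,
      time = t_grid,
      foci = lapply(seq_len(n_foci), function(fi) {
        lam <- lambda[[fi]]
        list(frequency = spec$beats[[fi]]$frequency,
             amplitude = spec$beats[[fi]]$amplitude,
             duty_fraction = spec$beats[[fi]]$duty_fraction,
             center = spec$centers[fi, ],
             base_radius = spec$base_radius[fi],
             s = s_list[[fi]],
             lambda = lam,
             radius = spec$base_radius[fi] * lam,
             area = pi * (spec$base_radius[fi] * lam)^2,
             mean_divergence = 2 * (lam[-1] / lam[-n_t] - 1))
      })
    )
    class(truth) <- "ground_truth"
    list(stack = frame_stack(frames, spec$frame_rate), truth = truth)
  })
}

#' Generate a speckle frame pair with a known displacement
#'
#' The second frame is the first displaced by exactly `shift` (Fourier
#' shift, so subpixel values are exact up to interpolation band limits);
#' both frames share the same noise realization, which is shifted with
#' the texture.
#'
#' @param shift c(dx, dy) displacement in px of frame B relative to frame
#'   A (dx = columns, dy = rows). Must satisfy `|shift| < image_size/4`.
#' @param image_size c(height, width) in px.
#' @param noise_sd additive noise baked into the texture before shifting
#'   (texture contrast is 1, so `noise_sd = 0.1` is SNR 10).
#' @param seed integer seed.
#' @return list with `frame_a`, `frame_b` (matrices) and `truth`
#'   (list with `shift`).
#' @export
gen_speckle_pair <- function(shift, image_size = c(128, 128),
                             noise_sd = 0, seed = 1) {
  if (any(abs(shift) >= min(image_size) / 4))
    stop("|shift| must be below a quarter of the image size")
  with_seed(seed, {
    a <- speckle_texture(image_size[1], image_size[2])
    if (noise_sd > 0)
      a <- a + matrix(stats::rnorm(prod(image_size), sd = noise_sd),
                      image_size[1], image_size[2])
    b <- fourier_shift(a, shift)
    truth <- structure(list(shift = shift, seed = seed), class = "ground_truth")
    list(frame_a = a, frame_b = b, truth = truth)
  })
}
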