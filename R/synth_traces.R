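# Synthetic fluorescence calcium transients and spontaneous action
# potential trains with analytic ground truth.

#' Specify a synthetic calcium recording
#'
#' Each beat is a linear rise over `rise_time` from baseline to
#' `baseline * (1 + peak_dF)`, followed by exponential decay with time
#' constant `tau_decay`. Optional photobleaching multiplies the whole
#' fluorophore signal by `exp(-bleach_rate * t)`.
#'
#' Transients must resolve between beats
#' (`rise_time + 3 * tau_decay < 1 / beat_frequency`) so that per-beat
#' kinetics are recoverable.
#'
#' @param beat_frequency beats per second (Hz).
#' @param tau_decay decay time constant (s).
#' @param rise_time upstroke duration (s).
#' @param peak_dF peak amplitude as a fraction of baseline (dF/F).
#' @param baseline resting fluorescence (intensity units).
#' @param background_level additive background fluorescence.
#' @param bleach_rate photobleaching rate (fraction/s).
#' @param noise_sd additive Gaussian noise (intensity units); the
#'   transient amplitude is `baseline * peak_dF`, so SNR =
#'   `baseline * peak_dF / noise_sd`.
#' @param duration recording length (s).
#' @param frame_rate sampling rate (frames/s); at least 50 is advised
#'   for kinetic fixtures.
#' @param onset_delay time before the first beat (s); recordings start
#'   in diastole so the first upstroke is observable.
#' @param seed integer seed.
#' @return a `synthetic_calcium_spec` list.
#' @export
synthetic_calcium_spec <- function(beat_frequency = 1, tau_decay = 0.3,
                                   rise_time = 0.05, peak_dF = 1,
                                   baseline = 100, background_level = 0,
                                   bleach_rate = 0, noise_sd = 0,
                                   duration = 5, frame_rate = 100,
                                   onset_delay = 0.1, seed = 1) {
  if (beat_frequency <= 0 || tau_decay <= 0 || rise_time <= 0)
    stop("beat_frequency, tau_decay and rise_time must be positive")
  if (rise_time + 3 * tau_decay >= 1 / beat_frequency)
    stop("unresolvable transients: need rise_time + 3*tau_decay < 1/beat_frequency")
  if (frame_rate < 50)
    warning("frame_rate below 50 frames/s; kinetic metrics may be coarse")
  structure(list(beat_frequency = beat_frequency, tau_decay = tau_decay,
                 rise_time = rise_time, peak_dF = peak_dF,
                 baseline = baseline, background_level = background_level,
                 bleach_rate = bleach_rate, noise_sd = noise_sd,
                 duration = duration, frame_rate = frame_rate,
                 onset_delay = onset_delay, seed = seed),
            class = "synthetic_calcium_spec")
}

# Noise-free unit transient activation g(t) in [0, 1]: piecewise per
# beat, linear rise then exponential decay, restarting at each beat;
# zero before the first beat.
calcium_activation <- function(spec, t) {
  period <- 1 / spec$beat_frequency
  u <- (t - spec$onset_delay) %% period
  g <- ifelse(u < spec$rise_time,
              u / spec$rise_time,
              exp(-(u - spec$rise_time) / spec$tau_decay))
  g[t < spec$onset_delay] <- 0
  g
}

#' Generate a synthetic calcium trace (or image stack)
#'
#' @param spec a [synthetic_calcium_spec()].
#' @param as_stack if TRUE, render a small fluorescence [frame_stack()]
#'   (bright region-of-interest disk over uniform background) instead of
#'   a bare trace; use with [extract_corrected_trace()].
#' @param image_size c(height, width) in px when `as_stack = TRUE`.
#' @return list with `trace` (data.frame `time_s`, `value`; the
#'   region-of-interest fluorescence including background), optionally
#'   `stack`, `roi`, `background_roi` (logical matrices), and `truth`:
#'   per-beat start/peak times and the analytic time to peak
#'   (`0.9 * rise_time`, from the 10 percent-above-baseline crossing),
#'   FWHM (`0.5 * rise_time + tau_decay * log(2)`) and tau.
#' @export
gen_calcium_trace <- function(spec, as_stack = FALSE, image_size = c(32, 32)) {
  stopifnot(inherits(spec, "synthetic_calcium_spec"))
  with_seed(spec$seed, {
    n <- round(spec$duration * spec$frame_rate)
    t <- (seq_len(n) - 1) / spec$frame_rate
    g <- calcium_activation(spec, t)
    fluor <- spec$baseline * (1 + spec$peak_dF * g) *
      exp(-spec$bleach_rate * t)
    value <- spec$background_level + fluor
    if (spec$noise_sd > 0) value <- value + stats::rnorm(n, sd = spec$noise_sd)

    period <- 1 / spec$beat_frequency
    n_beats <- floor((spec$duration - spec$onset_delay - 1e-12) / period) + 1L
    beat_start <- spec$onset_delay + (seq_len(n_beats) - 1) * period
    truth <- structure(list(
      seed = spec$seed,
      beat_start = beat_start,
      peak_time = beat_start + spec$rise_time,
      time_to_peak = 0.9 * spec$rise_time,
      fwhm = 0.5 * spec$rise_time + spec$tau_decay * log(2),
      tau = spec$tau_decay,
      amplitude = spec$baseline * spec$peak_dF,
      baseline = spec$background_level + spec$baseline
    ), class = "ground_truth")

    out <- list(trace = data.frame(time_s = t, value = value), truth = truth)
    if (as_stack) {
      h <- image_size[1]; w <- image_size[2]
      ctr <- (image_size + 1) / 2
      rows <- matrix(seq_len(h), h, w)
      cols <- matrix(seq_len(w), h, w, byrow = TRUE)
      roi <- sqrt((rows - ctr[1])^2 + (cols - ctr[2])^2) <= min(image_size) / 4
      bg_roi <- sqrt((rows - 1)^2 + (cols - 1)^2) <= min(image_size) / 4
      bg_roi <- bg_roi & !roi
      frames <- array(0, dim = c(h, w, n))
      for (i in seq_len(n)) {
        f <- matrix(spec$background_level, h, w)
        f[roi] <- spec$background_level + fluor[i]
        if (spec$noise_sd > 0)
          f <- f + matrix(stats::rnorm(h * w, sd = spec$noise_sd), h, w)
        frames[, , i] <- f
      }
      out$stack <- frame_stack(frames, spec$frame_rate)
      out$roi <- roi
      out$background_roi <- bg_roi
    }
    out
  })
}

#' Specify a synthetic spontaneous action-potential train
#'
#' Two phenomenological morphologies are provided, mirroring the two cell
#' classes seen in conditioned cardiomyocyte cultures: `ventricular_like`
#' (plateau-bearing, moderate upstroke velocity) and `rapid_depolarizer`
#' (steep upstroke, short action potential, less negative maximum
#' diastolic potential). Defaults for the upstroke velocity are
#' 24 mV/ms (ventricular-like) and 88 mV/ms (rapid depolarizer).
#'
#' @param morphology `"ventricular_like"` or `"rapid_depolarizer"`.
#' @param mdp maximum diastolic potential (mV).
#' @param peak peak voltage (mV).
#' @param dvdt_max maximal upstroke velocity (mV/ms).
#' @param apd30,apd50,apd90 action potential durations (ms) at 30/50/90
#'   percent repolarization of the peak-to-MDP amplitude, measured from
#'   the time of maximal upstroke velocity.
#' @param rate spontaneous firing rate (Hz).
#' @param phase4_slope diastolic (phase-4) depolarization slope (mV/s).
#' @param sampling_rate samples per second.
#' @param n_beats number of beats to generate.
#' @param noise_sd additive Gaussian voltage noise (mV).
#' @param seed integer seed.
#' @return a `synthetic_ap_spec` list.
#' @export
synthetic_ap_spec <- function(morphology = c("ventricular_like",
                                             "rapid_depolarizer"),
                              mdp = NULL, peak = NULL, dvdt_max = NULL,
                              apd30 = NULL, apd50 = NULL, apd90 = NULL,
                              rate = NULL, phase4_slope = NULL,
                              sampling_rate = 10000, n_beats = 5,
                              noise_sd = 0, seed = 1) {
  morphology <- match.arg(morphology)
  def <- if (morphology == "ventricular_like") {
    list(mdp = -60, peak = 30, dvdt_max = 24, apd30 = 180, apd50 = 250,
         apd90 = 400, rate = 1, phase4_slope = 15)
  } else {
    list(mdp = -50, peak = 30, dvdt_max = 88, apd30 = 60, apd50 = 100,
         apd90 = 160, rate = 2, phase4_slope = 25)
  }
  spec <- list(morphology = morphology,
               mdp = mdp %||% def$mdp, peak = peak %||% def$peak,
               dvdt_max = dvdt_max %||% def$dvdt_max,
               apd30 = apd30 %||% def$apd30, apd50 = apd50 %||% def$apd50,
               apd90 = apd90 %||% def$apd90, rate = rate %||% def$rate,
               phase4_slope = phase4_slope %||% def$phase4_slope,
               sampling_rate = sampling_rate, n_beats = n_beats,
               noise_sd = noise_sd, seed = seed)
  if (!(spec$apd30 < spec$apd50 && spec$apd50 < spec$apd90))
    stop("need apd30 < apd50 < apd90")
  if (spec$apd90 >= 1000 / spec$rate)
    stop("infeasible morphology: apd90 must be below the cycle length")
  if (spec$mdp >= spec$peak) stop("need mdp < peak")
  if (spec$dvdt_max <= 0) stop("dvdt_max must be positive")
  class(spec) <- "synthetic_ap_spec"
  spec
}

# Lay out one action-potential cycle (noise free). Returns the segment
# boundaries and a function of the cycle-local time u in [0, T).
ap_cycle_model <- function(spec) {
  T_cyc <- 1 / spec$rate
  a30 <- spec$apd30 / 1000; a50 <- spec$apd50 / 1000; a90 <- spec$apd90 / 1000
  S <- spec$dvdt_max * 1000            # mV/s
  eps <- 1 / (1 + exp(6))              # logistic truncation at +/- 6k
  tail <- min(0.1 * T_cyc, 0.5 * (T_cyc - a90))

  # take-off depends on the diastolic interval, which depends (weakly)
  # on the upstroke width; two fixed-point iterations suffice
  takeoff <- spec$mdp + spec$phase4_slope * (T_cyc - a90 - tail)
  for (i in 1:2) {
    amp_up <- spec$peak - takeoff
    k <- amp_up / (4 * S * (1 - 2 * eps))
    du <- 12 * k
    d_dia <- T_cyc - du / 2 - (a90 + tail)
    if (d_dia <= 0)
      stop("infeasible morphology: repolarization leaves no diastolic interval")
    takeoff <- spec$mdp + spec$phase4_slope * d_dia
  }
  if (takeoff >= spec$peak || takeoff <= spec$mdp)
    stop("infeasible morphology: take-off potential outside (mdp, peak)")
  t0 <- d_dia + du / 2                 # upstroke centre (time of dV/dt max)
  if (du / 2 >= a30)
    stop("infeasible morphology: upstroke wider than apd30")

  amp <- spec$peak - spec$mdp
  v_lev <- spec$peak - c(0.30, 0.50, 0.90) * amp
  # monotone repolarization through the forced APD crossings
  kn_t <- c(du / 2, a30, a50, a90, a90 + tail)
  kn_v <- c(spec$peak, v_lev, spec$mdp)
  repol <- stats::splinefun(kn_t, kn_v, method = "monoH.FC")

  eval_cycle <- function(u) {
    # u measured from cycle start (beginning of diastole)
    v <- numeric(length(u))
    dia <- u < d_dia
    v[dia] <- spec$mdp + spec$phase4_slope * u[dia]
    ups <- !dia & u < d_dia + du
    if (any(ups)) {
      x <- (u[ups] - t0) / k
      raw <- 1 / (1 + exp(-x))
      v[ups] <- takeoff + (spec$peak - takeoff) * (raw - eps) / (1 - 2 * eps)
    }
    rep_i <- !dia & !ups
    if (any(rep_i)) v[rep_i] <- repol(u[rep_i] - t0)
    v
  }
  list(T_cyc = T_cyc, d_dia = d_dia, du = du, k = k, t0 = t0,
       takeoff = takeoff, eval_cycle = eval_cycle)
}

#' Generate a spontaneous action-potential train
#'
#' Each cycle is built piecewise: a linear phase-4 ramp from the MDP at
#' `phase4_slope`, a sigmoidal upstroke whose maximal slope equals
#' `dvdt_max`, and a monotone cubic repolarization spline constructed to
#' cross the 30/50/90 percent repolarization levels at exactly
#' `apd30/apd50/apd90` after the time of maximal upstroke velocity.
#'
#' @param spec a [synthetic_ap_spec()].
#' @return list with `trace` (data.frame `time_s`, `voltage_mV`),
#'   `sampling_rate`, and `truth` with per-beat upstroke times and the
#'   exact mdp, peak, take-off potential, dvdt_max, APDs, phase-4 slope
#'   and rate.
#' @export
gen_ap_trace <- function(spec) {
  stopifnot(inherits(spec, "synthetic_ap_spec"))
  with_seed(spec$seed, {
    mod <- ap_cycle_model(spec)
    fs <- spec$sampling_rate
    n <- round(spec$n_beats * mod$T_cyc * fs)
    t <- (seq_len(n) - 1) / fs
    u <- t %% mod$T_cyc
    v <- mod$eval_cycle(u)
    if (spec$noise_sd > 0) v <- v + stats::rnorm(n, sd = spec$noise_sd)
    upstroke_times <- mod$t0 + (seq_len(spec$n_beats) - 1) * mod$T_cyc
    truth <- structure(list(
      seed = spec$seed,
      morphology = spec$morphology,
      upstroke_times = upstroke_times,
      mdp = spec$mdp, peak = spec$peak,
      peak_amplitude = spec$peak - spec$mdp,
      take_off_potential = mod$takeoff,
      dvdt_max = spec$dvdt_max,
      apd30 = spec$apd30, apd50 = spec$apd50, apd90 = spec$apd90,
      phase4_slope = spec$phase4_slope,
      rate = spec$rate,
      upstroke_scale_s = mod$k
    ), class = "ground_truth")
    list(trace = data.frame(time_s = t, voltage_mV = v),
         sampling_rate = fs, truth = truth)
  })
}
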