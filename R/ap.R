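# Action-potential channel: spontaneous AP detection in current-clamp
# voltage traces, per-AP feature extraction (peak, MDP, dV/dt_max,
# take-off potential, APD30/50/90, phase-4 slope, rate) and Tukey-fence
# classification of rapidly depolarizing cells.

#' Wrap a sampled voltage recording
#'
#' @param time_s time vector (s), uniformly sampled.
#' @param voltage_mV membrane voltage (mV).
#' @return a `voltage_trace` data.frame with attribute `sampling_rate`.
#' @export
voltage_trace <- function(time_s, voltage_mV) {
  stopifnot(length(time_s) == length(voltage_mV), length(time_s) >= 3L)
  dt <- diff(time_s)
  if (max(dt) - min(dt) > 1e-6 * stats::median(dt) + 1e-12)
    stop("voltage trace must be uniformly sampled")
  out <- data.frame(time_s = time_s, voltage_mV = voltage_mV)
  attr(out, "sampling_rate") <- 1 / stats::median(dt)
  class(out) <- c("voltage_trace", "data.frame")
  out
}

# Savitzky-Golay center-point smoothing (local polynomial fit), used on
# the dV/dt series: preserves smooth peaks far better than a box filter
# while still averaging noise.
sg_smooth <- function(y, half_width, degree = 2L) {
  m <- as.integer(half_width)
  n <- length(y)
  if (m < 1L || n < 2L * m + 1L) return(y)
  j <- -m:m
  X <- outer(j, 0:degree, `^`)
  cf <- solve(crossprod(X), t(X))[1, ]
  yp <- c(rev(y[seq_len(m)]), y, rev(y[n - seq_len(m) + 1L]))
  as.numeric(stats::filter(yp, rev(cf), sides = 2))[(m + 1L):(m + n)]
}

# Voltage-smoothing window in samples: 5 samples at 10 kHz (0.5 ms),
# scaled with the sampling rate.
ma_window_samples <- function(fs) max(1L, round(5 * fs / 10000))

# dV/dt series in mV/ms: central difference of the raw voltage, then
# Savitzky-Golay smoothing of the derivative (default ~0.2 ms
# half-width; event detection uses a wider window).
dvdt_series <- function(v, fs, half_width_ms = 0.2) {
  n <- length(v)
  d <- numeric(n)
  d[2:(n - 1)] <- (v[3:n] - v[1:(n - 2)]) * fs / 2
  d[1] <- (v[2] - v[1]) * fs
  d[n] <- (v[n] - v[n - 1]) * fs
  d <- d / 1000                      # mV/s -> mV/ms
  sg_smooth(d, half_width = max(1L, round(half_width_ms * 1e-3 * fs)))
}

# Peak upstroke velocity by a quadratic fit to the log-derivative around
# its maximum: the log of a sigmoidal upstroke's derivative is locally
# parabolic, so the fit is scale-free and adapts to both slow and very
# fast upstrokes without a fixed smoothing width. The fit region (top
# `top_fraction` of the peak) is selected on the smoothed derivative;
# the values fitted are the raw central differences, whose only
# systematic error is the chord-slope attenuation tanh(x)/x at
# x = dt / (2k); k, the upstroke time-scale, drops out of the fitted
# curvature, so that attenuation is divided back out. Implausible fits
# (vertex far from the observed maximum) fall back to the smoothed peak.
dvdt_peak_fit <- function(d_raw, d_smooth, top_fraction = 0.6) {
  n <- length(d_smooth)
  j <- which.max(d_smooth)
  out <- list(value = d_smooth[j], index = j)
  if (d_smooth[j] <= 0) return(out)
  thr <- top_fraction * d_smooth[j]
  lo <- j; while (lo > 1L && d_smooth[lo - 1L] > thr) lo <- lo - 1L
  hi <- j; while (hi < n && d_smooth[hi + 1L] > thr) hi <- hi + 1L
  if (hi - lo < 4L) { lo <- max(1L, j - 2L); hi <- min(n, j + 2L) }
  seg <- lo:hi
  x <- seg - j
  y <- log(pmax(d_raw[seg], 1e-9 * d_smooth[j]))
  X <- cbind(1, x, x^2)
  cf <- tryCatch(solve(crossprod(X), crossprod(X, y)), error = function(e) NULL)
  if (is.null(cf) || !is.finite(cf[3]) || cf[3] >= 0) return(out)
  xv <- -cf[2] / (2 * cf[3])
  if (abs(xv) > (hi - lo)) return(out)
  value <- exp(cf[1] - cf[2]^2 / (4 * cf[3]))
  # chord-slope correction: curvature c2 = -1/(4 k^2) in sample units
  k_hat <- sqrt(-1 / (4 * cf[3]))
  xk <- 1 / (2 * k_hat)
  corr <- min(xk / tanh(xk), 1.1)
  value <- value * corr
  # a smooth peak can exceed its best raw sample only by the chord
  # attenuation and subsample offset, both O(1/k^2); this cap keeps a
  # flat-topped derivative (constant-slope upstroke) from being inflated
  # by its corners bending the parabola
  value <- min(value, max(d_raw[seg]) * (1 + 1 / (4 * k_hat^2)))
  if (value > 1.3 * d_smooth[j] || value < 0.75 * d_smooth[j]) return(out)
  list(value = value, index = j + xv)
}

# Final dV/dt_max estimate: median of the log-quadratic fit over three
# region widths. A noise spike can hijack the region selected at one
# threshold but not consistently at all three, so the median is robust
# to the heavy tail of single-fit estimates on slow noisy upstrokes.
dvdt_peak_estimate <- function(d_raw, d_smooth) {
  fits <- lapply(c(0.35, 0.45, 0.55), function(f)
    dvdt_peak_fit(d_raw, d_smooth, top_fraction = f))
  vals <- vapply(fits, `[[`, numeric(1), "value")
  med <- stats::median(vals)
  fits[[which.min(abs(vals - med))]]
}

# Interpolated downward level crossing, refined by a local linear fit of
# the raw voltage over +/- window samples around the approximate
# crossing (regression averages the noise a single-sample interpolation
# would inherit). Returns the crossing time or NA.
refined_down_crossing <- function(t, v_smooth, v_raw, seg, level, fs) {
  cr <- level_crossings(t[seg], v_smooth[seg], level, "down")
  if (!length(cr)) return(NA_real_)
  i0 <- seg[1] + max(1L, findInterval(cr[1], t[seg])) - 1L
  hw <- max(2L, round(1.5e-3 * fs))
  win <- max(seg[1], i0 - hw):min(seg[length(seg)], i0 + hw)
  if (length(win) < 5L) return(cr[1])
  fit <- stats::lm.fit(cbind(1, t[win]), v_raw[win])
  b <- fit$coefficients
  if (!is.finite(b[2]) || b[2] >= 0) return(cr[1])
  tc <- (level - b[1]) / b[2]
  if (tc < t[win[1]] - 2e-3 || tc > t[win[length(win)]] + 2e-3) return(cr[1])
  tc
}

#' Detect spontaneous action potentials
#'
#' Upstrokes are upward crossings of a dV/dt threshold on the smoothed
#' derivative, separated by at least `min_cycle`. For each upstroke the
#' peak is the voltage maximum within the following `0.5 * min_cycle`;
#' maximum diastolic potentials are voltage minima between consecutive
#' upstrokes (trace boundaries serve for the first/last event).
#'
#' @param trace a [voltage_trace()].
#' @param dvdt_threshold upstroke detection threshold (mV/ms).
#' @param min_cycle minimum cycle length (s).
#' @return an `ap_events` data.frame with sample indices `upstroke`,
#'   `peak`, `mdp_before`, `mdp_after` (one row per AP; possibly empty).
#' @export
detect_aps <- function(trace, dvdt_threshold = 10, min_cycle = 0.2) {
  stopifnot(inherits(trace, "voltage_trace"))
  fs <- attr(trace, "sampling_rate")
  v <- trace$voltage_mV
  n <- length(v)
  vs <- moving_average(v, ma_window_samples(fs))
  d <- dvdt_series(v, fs, half_width_ms = 0.5)
  above <- d > dvdt_threshold
  onsets <- which(above & !c(FALSE, above[-n]))
  # refractory: keep the first onset of each burst
  keep <- integer(0)
  last_t <- -Inf
  for (i in onsets) {
    if ((i - 1) / fs - last_t >= min_cycle) {
      keep <- c(keep, i)
      last_t <- (i - 1) / fs
    }
  }
  empty <- data.frame(upstroke = integer(0), peak = integer(0),
                      mdp_before = integer(0), mdp_after = integer(0))
  class(empty) <- c("ap_events", "data.frame")
  if (!length(keep)) return(empty)
  half_cycle <- max(2L, round(0.5 * min_cycle * fs))
  peaks <- vapply(keep, function(i) {
    hi <- min(n, i + half_cycle)
    i + which.max(vs[i:hi]) - 1L
  }, integer(1))
  n_ev <- length(keep)
  mdp_before <- integer(n_ev)
  mdp_after <- integer(n_ev)
  for (e in seq_len(n_ev)) {
    lo <- if (e == 1L) 1L else peaks[e - 1L]
    seg <- lo:keep[e]
    mdp_before[e] <- lo + which.min(vs[seg]) - 1L
    hi <- if (e == n_ev) n else keep[e + 1L]
    seg <- peaks[e]:hi
    mdp_after[e] <- peaks[e] + which.min(vs[seg]) - 1L
  }
  out <- data.frame(upstroke = keep, peak = peaks,
                    mdp_before = mdp_before, mdp_after = mdp_after)
  class(out) <- c("ap_events", "data.frame")
  out
}

#' Feature set of one action potential
#'
#' Computes the standard per-AP features. `dvdt_max` is the maximum of
#' the smoothed derivative on the upstroke (parabolic-refined); the
#' take-off potential is the voltage at the last sample before dV/dt
#' first exceeds `takeoff_fraction` of `dvdt_max`; APDx is the time from
#' the APD reference (default: time of dV/dt_max) to the interpolated
#' repolarization crossing of `peak - x% * (peak - MDP)`; the phase-4
#' slope is the least-squares slope over the middle 50 percent of the
#' MDP-to-take-off interval.
#'
#' @param trace a [voltage_trace()].
#' @param event one row of [detect_aps()] output.
#' @param apd_reference `"dvdt_max"` (APD measured from the time of
#'   maximal upstroke velocity) or `"peak"`.
#' @param takeoff_fraction fraction of dV/dt_max defining the take-off
#'   point (default 0.10); alternatively set `takeoff_threshold` to an
#'   absolute dV/dt in mV/ms.
#' @param takeoff_threshold optional absolute take-off threshold (mV/ms).
#' @return an `ap_metrics` list with `peak_voltage`, `mdp`,
#'   `peak_amplitude`, `dvdt_max` (mV/ms), `take_off_potential`,
#'   `apd30`, `apd50`, `apd90` (ms; `NA` with a flag when a level is
#'   never crossed), `phase4_slope` (mV/s), `cycle_length` and `rate`
#'   (`NA` at this level; filled by [analyze_ap_trace()]).
#' @export
ap_metrics <- function(trace, event, apd_reference = c("dvdt_max", "peak"),
                       takeoff_fraction = 0.10, takeoff_threshold = NULL) {
  apd_reference <- match.arg(apd_reference)
  stopifnot(inherits(trace, "voltage_trace"))
  fs <- attr(trace, "sampling_rate")
  t <- trace$time_s
  v <- trace$voltage_mV
  vs <- moving_average(v, ma_window_samples(fs))
  # wider window for diastolic levels: the MDP region is flat, so a 2 ms
  # average suppresses the min-of-noise bias without distorting the value
  vw <- moving_average(v, max(1L, round(2e-3 * fs)))
  d <- dvdt_series(v, fs)

  i_mdp <- event$mdp_before
  i_up <- event$upstroke
  i_pk <- event$peak
  i_mdp2 <- event$mdp_after
  stopifnot(i_mdp < i_pk, i_pk < i_mdp2)

  mdp_nb <- max(1L, i_mdp - round(5e-3 * fs)):min(length(v), i_mdp + round(5e-3 * fs))
  mdp <- min(vw[mdp_nb])
  peak_voltage <- vs[i_pk]
  amp <- peak_voltage - mdp

  up_seg <- i_mdp:i_pk
  d_raw <- c(0, diff(v)) * fs / 1000
  d_raw[up_seg] <- (v[pmin(up_seg + 1L, length(v))] -
                      v[pmax(up_seg - 1L, 1L)]) * fs / 2000
  pk_fit <- dvdt_peak_estimate(d_raw[up_seg], d[up_seg])
  dvdt_max <- pk_fit$value
  t_ref <- t[up_seg[1]] + (pk_fit$index - 1) / fs

  thr <- if (!is.null(takeoff_threshold)) takeoff_threshold
         else takeoff_fraction * dvdt_max
  # walk back from the derivative peak to its last sub-threshold sample;
  # searching forward instead would latch onto derivative noise ahead of
  # the true upstroke foot
  dw <- dvdt_series(v, fs, half_width_ms = 0.5)
  jj <- up_seg[min(length(up_seg), max(1L, round(pk_fit$index)))]
  while (jj > up_seg[1] && dw[jj - 1L] > thr) jj <- jj - 1L
  i_to <- max(up_seg[1], jj - 1L)
  take_off <- vs[i_to]

  ref_time <- if (apd_reference == "dvdt_max") t_ref else t[i_pk]
  rep_seg <- i_pk:i_mdp2
  apd <- vapply(c(30, 50, 90), function(x) {
    level <- peak_voltage - (x / 100) * amp
    tc <- refined_down_crossing(t, vs, v, rep_seg, level, fs)
    if (!is.finite(tc)) return(NA_real_)
    (tc - ref_time) * 1000
  }, numeric(1))

  # phase-4 slope: middle 50% of the MDP -> take-off interval
  p4 <- NA_real_
  if (i_to - i_mdp >= 4L) {
    lo <- i_mdp + round(0.25 * (i_to - i_mdp))
    hi <- i_mdp + round(0.75 * (i_to - i_mdp))
    if (hi - lo >= 2L) {
      seg <- lo:hi
      p4 <- unname(stats::coef(stats::lm(vs[seg] ~ t[seg]))[2])
    }
  }

  structure(list(peak_voltage = peak_voltage, mdp = mdp,
                 peak_amplitude = amp, dvdt_max = dvdt_max,
                 take_off_potential = take_off,
                 apd30 = apd[1], apd50 = apd[2], apd90 = apd[3],
                 phase4_slope = p4,
                 cycle_length = NA_real_, rate = NA_real_,
                 apd_reference = apd_reference, ref_time = ref_time),
            class = "ap_metrics")
}

#' Spontaneous firing rate from detected APs
#'
#' @param events an `ap_events` data.frame from [detect_aps()].
#' @param duration recording duration (s).
#' @param sampling_rate samples per second (needed to convert upstroke
#'   indices to times; taken from the attribute if `events` carries one).
#' @return list with `rate` (count/duration, Hz), `rate_interval`
#'   (1/median cycle length; `NA` with fewer than two events) and
#'   `n_aps`.
#' @export
spontaneous_rate <- function(events, duration, sampling_rate) {
  if (duration <= 0) stop("`duration` must be positive")
  n <- nrow(events)
  r_count <- n / duration
  r_int <- if (n >= 2) {
    tt <- (events$upstroke - 1) / sampling_rate
    1 / stats::median(diff(tt))
  } else NA_real_
  list(rate = r_count, rate_interval = r_int, n_aps = n)
}

#' Analyse a whole voltage trace
#'
#' Detects APs and extracts the feature set for each, filling per-AP
#' cycle length and rate from the upstroke spacing.
#'
#' @param trace a [voltage_trace()].
#' @param ... passed to [detect_aps()] and [ap_metrics()] (arguments are
#'   routed by name).
#' @return list with `events`, `metrics` (data.frame, one row per AP)
#'   and `rate` (from [spontaneous_rate()]).
#' @export
analyze_ap_trace <- function(trace, ...) {
  dots <- list(...)
  det_args <- dots[names(dots) %in% c("dvdt_threshold", "min_cycle")]
  met_args <- dots[names(dots) %in% c("apd_reference", "takeoff_fraction",
                                      "takeoff_threshold")]
  fs <- attr(trace, "sampling_rate")
  events <- do.call(detect_aps, c(list(trace), det_args))
  dur <- nrow(trace) / fs
  rate <- spontaneous_rate(events, dur, fs)
  if (!nrow(events))
    return(list(events = events, metrics = data.frame(), rate = rate))
  cyc <- c(diff((events$upstroke - 1) / fs), NA_real_)
  rows <- lapply(seq_len(nrow(events)), function(i) {
    m <- do.call(ap_metrics, c(list(trace, events[i, ]), met_args))
    data.frame(ap = i, peak_voltage = m$peak_voltage, mdp = m$mdp,
               peak_amplitude = m$peak_amplitude, dvdt_max = m$dvdt_max,
               take_off_potential = m$take_off_potential,
               apd30 = m$apd30, apd50 = m$apd50, apd90 = m$apd90,
               phase4_slope = m$phase4_slope,
               cycle_length = cyc[i],
               rate = ifelse(is.na(cyc[i]), NA_real_, 1 / cyc[i]))
  })
  list(events = events, metrics = do.call(rbind, rows), rate = rate)
}

#' Tukey-fence classification of rapid depolarizers
#'
#' A cell is a rapid depolarizer when its maximal upstroke velocity
#' exceeds `Q3 + 1.5 * IQR` of the cohort distribution. Quartiles use
#' linear interpolation between order statistics (quantile type 7);
#' the comparison is strict, so degenerate all-equal cohorts flag
#' nothing.
#'
#' @param values cohort of dV/dt_max values (mV/ms), length >= 4.
#' @return a `cohort_classification` list with `values`, `q1`, `q3`,
#'   `iqr`, `cutoff`, `flags` (logical) and `fraction_rapid`.
#' @export
classify_rapid_depolarizers <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 4L)
    stop("cohort too small: quartiles are unstable below 4 cells")
  if (any(!is.finite(values))) stop("cohort values must be finite")
  q <- stats::quantile(values, c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2] - q[1]
  cutoff <- q[2] + 1.5 * iqr
  flags <- values > cutoff
  structure(list(values = values, q1 = q[1], q3 = q[2], iqr = iqr,
                 cutoff = cutoff, flags = flags,
                 fraction_rapid = mean(flags)),
            class = "cohort_classification")
}

#' Group summary of AP metrics
#'
#' Per-group mean, standard error and n for every numeric AP feature,
#' plus the fraction of rapid depolarizers. By default the Tukey fence
#' is computed on the pooled cohort (all groups together), so that a
#' cell's classification does not depend on how the cohort is split;
#' `rapid_scope = "per_group"` applies the fence within each group.
#'
#' @param metrics data.frame with one row per cell, containing at least
#'   `dvdt_max`; other numeric columns are summarised too.
#' @param groups group label per row.
#' @param rapid_scope `"pooled"` or `"per_group"`.
#' @return list with `summary` (data.frame: group, metric, mean, sem,
#'   n) and `fraction_rapid` (named per group; `NA` when a group is too
#'   small to classify on its own).
#' @export
cohort_summary <- function(metrics, groups,
                           rapid_scope = c("pooled", "per_group")) {
  rapid_scope <- match.arg(rapid_scope)
  if (nrow(metrics) != length(groups)) stop("one group label per row required")
  if (!"dvdt_max" %in% names(metrics)) stop("`metrics` needs a dvdt_max column")
  groups <- as.character(groups)
  if (any(table(groups) < 1L)) stop("empty group")
  num_cols <- names(metrics)[vapply(metrics, is.numeric, logical(1))]
  rows <- list()
  for (g in unique(groups)) {
    sub <- metrics[groups == g, , drop = FALSE]
    for (cn in num_cols) {
      x <- sub[[cn]][is.finite(sub[[cn]])]
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, metric = cn,
        mean = if (length(x)) mean(x) else NA_real_,
        sem = sem(x), n = length(x))
    }
  }
  if (rapid_scope == "pooled") {
    cls <- classify_rapid_depolarizers(metrics$dvdt_max)
    fr <- vapply(unique(groups), function(g)
      mean(cls$flags[groups == g]), numeric(1))
  } else {
    fr <- vapply(unique(groups), function(g) {
      x <- metrics$dvdt_max[groups == g]
      if (length(x) < 4L) return(NA_real_)
      classify_rapid_depolarizers(x)$fraction_rapid
    }, numeric(1))
  }
  list(summary = do.call(rbind, rows),
       fraction_rapid = stats::setNames(fr, unique(groups)))
}
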