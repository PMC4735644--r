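# Calcium channel: background-corrected normalized fluorescence traces
# and per-beat transient kinetics (time to peak with the 10%-above-
# baseline rule, FWHM between half-maximum crossings, exponential decay
# time constant fitted from the peak to the start of the next beat).

#' Background-corrected fluorescence trace from an image stack
#'
#' For each frame, the mean background fluorescence is subtracted from
#' the mean signal in the region of interest; the corrected trace is
#' smoothed with a moving average and min-max normalized over the whole
#' recording.
#'
#' @param stack a fluorescence [frame_stack()].
#' @param roi logical matrix marking the beating area.
#' @param background_roi logical matrix marking a background area; must
#'   be disjoint from `roi`.
#' @param smoothing_window moving-average window in seconds (default 5
#'   samples at the stack frame rate); set 0 to disable.
#' @return a `corrected_trace` data.frame with `time_s`, `F_corrected`
#'   (smoothed, intensity units) and `F_norm` (min-max normalized to
#'   \[0, 1\]); the smoothing window used is stored as an attribute.
#' @export
extract_corrected_trace <- function(stack, roi, background_roi,
                                    smoothing_window = NULL) {
  stopifnot(inherits(stack, "frame_stack"))
  d <- dim(stack$frames)[1:2]
  if (!all(dim(roi) == d) || !all(dim(background_roi) == d))
    stop("ROI masks must match the frame size")
  if (!any(roi) || !any(background_roi)) stop("empty ROI")
  if (any(roi & background_roi)) stop("ROI and background ROI overlap")
  n <- n_frames(stack)
  f_roi <- vapply(seq_len(n), function(i) mean(stack$frames[, , i][roi]),
                  numeric(1))
  f_bg <- vapply(seq_len(n), function(i)
    mean(stack$frames[, , i][background_roi]), numeric(1))
  corrected <- f_roi - f_bg
  win <- if (is.null(smoothing_window)) 5L
         else max(1L, round(smoothing_window * stack$frame_rate))
  sm <- moving_average(corrected, win)
  rng <- range(sm)
  norm <- if (diff(rng) > 0) (sm - rng[1]) / diff(rng) else rep(0, n)
  out <- data.frame(time_s = stack$time, F_corrected = sm, F_norm = norm)
  attr(out, "smoothing_samples") <- win
  attr(out, "frame_interval") <- stack$frame_interval
  class(out) <- c("corrected_trace", "data.frame")
  out
}

#' Wrap a 1-D trace as a corrected trace
#'
#' For traces already extracted elsewhere (e.g. a two-column CSV), this
#' applies the same smoothing and min-max normalization as
#' [extract_corrected_trace()].
#'
#' @param time_s,value numeric vectors of equal length.
#' @param smoothing_samples moving-average window in samples (1 = off).
#' @return a `corrected_trace` data.frame.
#' @export
as_corrected_trace <- function(time_s, value, smoothing_samples = 1L) {
  stopifnot(length(time_s) == length(value))
  sm <- moving_average(value, smoothing_samples)
  rng <- range(sm)
  norm <- if (diff(rng) > 0) (sm - rng[1]) / diff(rng) else rep(0, length(sm))
  out <- data.frame(time_s = time_s, F_corrected = sm, F_norm = norm)
  attr(out, "smoothing_samples") <- as.integer(smoothing_samples)
  attr(out, "frame_interval") <- stats::median(diff(time_s))
  class(out) <- c("corrected_trace", "data.frame")
  out
}

#' Construct a transient window by hand
#'
#' @param start,end first and one-past-last sample indices of the beat
#'   window (the window is `[start, end)` in samples).
#' @param peak sample index of the transient peak (inside the window).
#' @param baseline pre-transient baseline level (trace units).
#' @return a `transient_window` list.
#' @export
transient_window <- function(start, end, peak, baseline) {
  if (!(start <= peak && peak < end)) stop("peak must lie inside the window")
  structure(list(start = as.integer(start), end = as.integer(end),
                 peak = as.integer(peak), baseline = baseline),
            class = "transient_window")
}

#' Split a corrected trace into per-beat transient windows
#'
#' Transient peaks are located first (local maxima above half the global
#' amplitude, separated by `min_interval`); each beat window then starts
#' at the last upward crossing of
#' `baseline + threshold_fraction * amplitude` before its peak and ends
#' at the start of the next beat. Anchoring windows on prominent peaks
#' keeps noise wiggles around the onset level from spawning spurious
#' beats. The baseline for each beat is the median of the last 10
#' percent of the previous window (the pre-transient plateau); the
#' global minimum serves for the first beat.
#'
#' @param trace a `corrected_trace`.
#' @param threshold_fraction fraction of the beat amplitude above
#'   baseline that defines the transient start (default 0.10).
#' @param min_interval minimum beat spacing in seconds.
#' @return list of [transient_window()]s (possibly empty).
#' @export
segment_transients <- function(trace, threshold_fraction = 0.10,
                               min_interval = 0.2) {
  y <- trace$F_corrected
  t <- trace$time_s
  n <- length(y)
  dt <- attr(trace, "frame_interval") %||% stats::median(diff(t))
  base0 <- stats::quantile(y, 0.1, names = FALSE)
  amp0 <- max(y) - base0
  if (amp0 <= 0) return(list())
  # prominent peaks, spaced by at least min_interval (higher one kept)
  peak_level <- base0 + 0.5 * amp0
  is_max <- c(FALSE, y[2:(n - 1)] >= y[1:(n - 2)] & y[2:(n - 1)] > y[3:n],
              FALSE)
  pk <- which(is_max & y > peak_level)
  if (!length(pk)) return(list())
  ord <- order(y[pk], decreasing = TRUE)
  acc <- integer(0)
  for (i in ord) {
    if (!length(acc) || all(abs(t[pk[i]] - t[pk[acc]]) >= min_interval))
      acc <- c(acc, i)
  }
  pk <- sort(pk[acc])
  # beat onset: last upward crossing of the threshold level before each peak
  level <- base0 + threshold_fraction * amp0
  d <- y - level
  up <- which(d[-n] < 0 & d[-1] >= 0)   # sample before an upward crossing
  on_idx <- vapply(pk, function(p) {
    before <- up[up < p]
    if (length(before)) before[length(before)] + 1L else 1L
  }, integer(1))
  keep <- !duplicated(on_idx)
  on_idx <- on_idx[keep]
  bounds <- c(on_idx, n + 1L)
  windows <- vector("list", length(on_idx))
  for (i in seq_along(on_idx)) {
    s <- bounds[i]; e <- bounds[i + 1L]
    seg <- y[s:(e - 1L)]
    pk <- s + which.max(seg) - 1L
    if (i == 1L) {
      baseline <- min(y)
    } else {
      prev <- y[bounds[i - 1L]:(s - 1L)]
      tail_n <- max(1L, ceiling(length(prev) * 0.1))
      baseline <- stats::median(utils::tail(prev, tail_n))
    }
    windows[[i]] <- transient_window(s, e, pk, baseline)
  }
  windows
}

#' Time to peak of a calcium transient
#'
#' Time from the upward crossing of 10 percent of the transient
#' amplitude above baseline (linearly interpolated between samples) to
#' the peak sample.
#'
#' @param window a [transient_window()].
#' @param trace the `corrected_trace` the window refers to.
#' @param threshold_fraction crossing level as a fraction of the
#'   peak-above-baseline amplitude (default 0.10).
#' @return time to peak in seconds; 0 with attribute `degenerate = TRUE`
#'   when the peak sits at the window start.
#' @export
time_to_peak <- function(window, trace, threshold_fraction = 0.10) {
  stopifnot(inherits(window, "transient_window"))
  t <- trace$time_s; y <- trace$F_corrected
  if (window$peak == window$start)
    return(structure(0, degenerate = TRUE))
  seg <- window$start:window$peak
  amp <- y[window$peak] - window$baseline
  if (amp <= 0) return(structure(0, degenerate = TRUE))
  level <- window$baseline + threshold_fraction * amp
  cr <- level_crossings(t[seg], y[seg], level, "up")
  t_cross <- if (length(cr)) cr[length(cr)] else t[window$start]
  t[window$peak] - t_cross
}

#' Full width at half maximum of a calcium transient
#'
#' Time between the interpolated crossings of half the peak-above-
#' baseline amplitude on the rising and falling flanks.
#'
#' @param window a [transient_window()].
#' @param trace the `corrected_trace` the window refers to.
#' @return FWHM in seconds, or `NA` with attribute `flag` when the
#'   downstroke never falls back to the half-maximum level inside the
#'   window.
#' @export
fwhm <- function(window, trace) {
  stopifnot(inherits(window, "transient_window"))
  t <- trace$time_s; y <- trace$F_corrected
  amp <- y[window$peak] - window$baseline
  if (amp <= 0) return(structure(NA_real_, flag = "no_amplitude"))
  level <- window$baseline + 0.5 * amp
  up_seg <- window$start:window$peak
  dn_seg <- window$peak:(window$end - 1L)
  up <- level_crossings(t[up_seg], y[up_seg], level, "up")
  dn <- level_crossings(t[dn_seg], y[dn_seg], level, "down")
  if (!length(up)) up <- t[window$start]
  if (!length(dn)) return(structure(NA_real_, flag = "incomplete_downstroke"))
  dn[1] - up[length(up)]
}

#' Exponential decay time constant of a calcium transient
#'
#' Fits `F(t) = baseline + A * exp(-t / tau)` by nonlinear least squares
#' on the samples from the peak to the end of the window (the start of
#' the next beat), with `t` zeroed at the peak. The asymptote `baseline`
#' is a free parameter initialized at the window baseline: holding it
#' fixed would bias tau whenever the previous transient has not fully
#' decayed by the start of the beat. Starting values:
#' `A = peak - baseline`, `tau` = time for the trace to fall to `1/e` of
#' the amplitude.
#'
#' @param window a [transient_window()].
#' @param trace the `corrected_trace` the window refers to.
#' @return list with `A`, `tau` (s), `r_squared` and `converged`;
#'   non-convergence or a non-positive fitted tau gives
#'   `converged = FALSE` and `tau = NA`.
#' @export
fit_decay_tau <- function(window, trace) {
  stopifnot(inherits(window, "transient_window"))
  seg <- window$peak:(window$end - 1L)
  if (length(seg) < 5L)
    return(list(A = NA_real_, tau = NA_real_, r_squared = NA_real_,
                converged = FALSE, reason = "fewer than 5 decay samples"))
  tt <- trace$time_s[seg] - trace$time_s[window$peak]
  yy <- trace$F_corrected[seg]
  A0 <- yy[1] - window$baseline
  if (!is.finite(A0) || A0 <= 0 || stats::sd(yy) == 0)
    return(list(A = NA_real_, tau = NA_real_, r_squared = NA_real_,
                converged = FALSE, reason = "no decaying amplitude"))
  below <- which(yy - window$baseline <= A0 / exp(1))
  tau0 <- if (length(below)) max(tt[below[1]], 3 * (tt[2] - tt[1]))
          else max(tt) / 2
  fit <- tryCatch(
    minpack.lm::nlsLM(yy ~ b + A * exp(-tt / tau),
                      start = list(b = window$baseline, A = A0, tau = tau0),
                      lower = c(b = -Inf, A = 0, tau = 1e-6),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit))
    return(list(A = NA_real_, tau = NA_real_, r_squared = NA_real_,
                converged = FALSE, reason = "fit did not converge"))
  cf <- stats::coef(fit)
  if (!is.finite(cf[["tau"]]) || cf[["tau"]] <= 0)
    return(list(A = NA_real_, tau = NA_real_, r_squared = NA_real_,
                converged = FALSE, reason = "non-positive tau"))
  ss_res <- sum(stats::resid(fit)^2)
  ss_tot <- sum((yy - mean(yy))^2)
  list(A = unname(cf[["A"]]), tau = unname(cf[["tau"]]),
       baseline_fit = unname(cf[["b"]]),
       r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_,
       converged = TRUE)
}

#' Per-beat transient metrics for a whole trace
#'
#' Convenience wrapper: segments the trace into beats and computes time
#' to peak, FWHM and the decay fit for each.
#'
#' @param trace a `corrected_trace`.
#' @param ... passed to [segment_transients()].
#' @return data.frame with one row per beat: `beat`, `time_to_peak_s`,
#'   `fwhm_s`, `tau_s`, `A`, `r_squared`.
#' @export
transient_metrics <- function(trace, ...) {
  wins <- segment_transients(trace, ...)
  if (!length(wins))
    return(data.frame(beat = integer(0), time_to_peak_s = numeric(0),
                      fwhm_s = numeric(0), tau_s = numeric(0),
                      A = numeric(0), r_squared = numeric(0)))
  rows <- lapply(seq_along(wins), function(i) {
    w <- wins[[i]]
    fit <- fit_decay_tau(w, trace)
    data.frame(beat = i,
               time_to_peak_s = as.numeric(time_to_peak(w, trace)),
               fwhm_s = as.numeric(fwhm(w, trace)),
               tau_s = fit$tau, A = fit$A, r_squared = fit$r_squared)
  })
  do.call(rbind, rows)
}
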