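# Contractility channel: threshold-segment a beating-aggregate video,
# trace the fractional area change over time, detect beats as minima of
# the fractional area (the object shrinks on contraction) and estimate
# the spontaneous beating frequency.

#' Segment a frame stack into per-frame object masks
#'
#' Thresholds every frame and keeps the largest connected component, so
#' debris and background speckle do not contribute to the area trace.
#' The default policy computes an Otsu threshold on the median frame and
#' applies it to all frames: deterministic, and robust to per-frame
#' noise.
#'
#' @param stack a [frame_stack()].
#' @param policy `"otsu"` (Otsu on the temporal median frame),
#'   `"quantile"` (threshold at the `quantile_prob` intensity quantile of
#'   the median frame) or `"fixed"` (user-supplied threshold).
#' @param threshold threshold for `policy = "fixed"`.
#' @param offset additive user offset applied to the computed threshold.
#' @param quantile_prob probability for the quantile policy.
#' @param roi optional logical matrix restricting segmentation to a
#'   region of interest; pixels outside are never part of the mask and
#'   the threshold is computed from inside pixels only.
#' @return a `mask_stack`: list with `masks` (H x W x T logical array),
#'   `threshold` (per-frame threshold used), and `empty_frames` (indices
#'   of frames whose mask came out empty; a warning is issued when any).
#' @export
segment_stack <- function(stack, policy = c("otsu", "quantile", "fixed"),
                          threshold = NULL, offset = 0,
                          quantile_prob = 0.5, roi = NULL) {
  policy <- match.arg(policy)
  stopifnot(inherits(stack, "frame_stack"))
  d <- dim(stack$frames)
  if (!is.null(roi)) {
    if (!all(dim(roi) == d[1:2])) stop("`roi` must match the frame size")
    if (!any(roi)) stop("`roi` is empty")
  }
  med_frame <- apply(stack$frames, c(1, 2), stats::median)
  vals <- if (is.null(roi)) med_frame else med_frame[roi]
  thr <- switch(policy,
    otsu = otsu_threshold(vals) + offset,
    quantile = stats::quantile(vals, quantile_prob, names = FALSE) + offset,
    fixed = {
      if (is.null(threshold)) stop("policy 'fixed' needs `threshold`")
      threshold + offset
    })

  masks <- array(FALSE, dim = d)
  empty <- integer(0)
  prev_centroid <- NULL
  for (ti in seq_len(d[3])) {
    bw <- stack$frames[, , ti] > thr
    if (!is.null(roi)) bw <- bw & roi
    if (!any(bw)) {
      empty <- c(empty, ti)
      next
    }
    lab <- EBImage::bwlabel(bw)
    sizes <- tabulate(lab[lab > 0])
    biggest <- which(sizes == max(sizes))
    if (length(biggest) > 1L && !is.null(prev_centroid)) {
      # tie: keep the component closest to the previous frame's centroid
      dists <- vapply(biggest, function(lb) {
        idx <- which(lab == lb, arr.ind = TRUE)
        sum((colMeans(idx) - prev_centroid)^2)
      }, numeric(1))
      biggest <- biggest[which.min(dists)]
    } else {
      biggest <- biggest[1]
    }
    keep <- lab == biggest
    idx <- which(keep, arr.ind = TRUE)
    prev_centroid <- colMeans(idx)
    masks[, , ti] <- keep
  }
  if (length(empty))
    warning(sprintf("%d frame(s) produced an empty mask", length(empty)))
  structure(list(masks = masks, threshold = rep(thr, d[3]),
                 policy = policy, empty_frames = empty),
            class = "mask_stack")
}

#' Fractional-area-change trace from a mask stack
#'
#' Counts mask pixels per frame and normalizes to the maximum over the
#' recording, the fractional area change. Dips in the fractional trace
#' mark contractions.
#'
#' @param masks a `mask_stack` from [segment_stack()].
#' @param stack the matching [frame_stack()] (for the time base and
#'   pixel size).
#' @return an `area_trace`: data.frame with columns `time_s`, `area_px2`,
#'   `fractional` (and `area_um2` when the stack has a pixel size);
#'   attribute `frame_interval`.
#' @export
area_trace <- function(masks, stack) {
  stopifnot(inherits(masks, "mask_stack"), inherits(stack, "frame_stack"))
  n_t <- dim(masks$masks)[3]
  if (n_t != n_frames(stack)) stop("mask stack and frame stack differ in length")
  area <- vapply(seq_len(n_t), function(i) sum(masks$masks[, , i]), numeric(1))
  if (max(area) == 0) stop("all masks are empty; no object to trace")
  tr <- data.frame(time_s = stack$time, area_px2 = area,
                   fractional = area / max(area))
  if (!is.null(stack$pixel_size))
    tr$area_um2 <- area * stack$pixel_size^2
  attr(tr, "frame_interval") <- stack$frame_interval
  class(tr) <- c("area_trace", "data.frame")
  tr
}

#' Detect beats as minima of the fractional area trace
#'
#' The fractional trace is smoothed with a short moving average; local
#' minima whose contraction depth (local baseline minus trace value)
#' reaches `min_depth` are kept, and events closer than `refractory`
#' seconds are merged, keeping the deeper one.
#'
#' @param trace an [area_trace()] (or any data.frame with `time_s` and
#'   `fractional`).
#' @param min_depth minimum contraction depth (dimensionless fraction of
#'   maximal area). The effective threshold is raised automatically to
#'   eight times the robust noise level of the smoothed trace (median
#'   absolute successive difference / sqrt(2)), so segmentation jitter
#'   does not masquerade as beats.
#' @param refractory minimum time between events (s).
#' @param smoothing_window moving-average window (s); default 3 frames.
#' @return a `beat_events` list with `peak_times` (s, times of maximum
#'   contraction), `depths`, and `indices` into the trace.
#' @export
detect_beats <- function(trace, min_depth = 0.01, refractory = 0.25,
                         smoothing_window = NULL) {
  y <- trace$fractional
  t <- trace$time_s
  if (length(y) < 3L) stop("trace too short for beat detection")
  dt <- stats::median(diff(t))
  win <- if (is.null(smoothing_window)) 3L else max(1L, round(smoothing_window / dt))
  ys <- moving_average(y, win)
  n <- length(ys)
  cand <- which(ys[2:(n - 1)] <= ys[1:(n - 2)] & ys[2:(n - 1)] <= ys[3:n]) + 1L
  # drop flat-plateau duplicates: keep first sample of equal runs
  if (length(cand) > 1L)
    cand <- cand[c(TRUE, diff(cand) > 1L | ys[cand[-1]] != ys[cand[-length(cand)]])]
  if (!length(cand))
    return(structure(list(peak_times = numeric(0), depths = numeric(0),
                          indices = integer(0)), class = "beat_events"))
  half <- max(1L, round(refractory / dt))
  depth <- vapply(cand, function(i) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    max(ys[lo:hi]) - ys[i]
  }, numeric(1))
  noise <- stats::mad(diff(ys)) / sqrt(2)
  min_depth <- max(min_depth, 8 * noise)
  keep <- depth >= min_depth
  cand <- cand[keep]; depth <- depth[keep]
  # refractory rule: greedily accept the deepest events first
  ord <- order(depth, decreasing = TRUE)
  accepted <- integer(0)
  for (i in ord) {
    if (!length(accepted) || all(abs(t[cand[i]] - t[cand[accepted]]) >= refractory))
      accepted <- c(accepted, i)
  }
  accepted <- sort(cand[accepted])
  structure(list(peak_times = t[accepted],
                 depths = depth[match(accepted, cand)],
                 indices = accepted),
            class = "beat_events")
}

#' Beating frequency from detected beats
#'
#' Two estimators are reported: the event count divided by the recording
#' duration (robust to a single missed beat) and the inverse median
#' inter-beat interval (robust to boundary effects). With fewer than two
#' events the interval estimate is `NA`.
#'
#' @param events a `beat_events` from [detect_beats()].
#' @param duration recording duration (s).
#' @return a `frequency_estimate` list with `frequency` (Hz, the count
#'   method), `frequency_interval` (Hz, inverse median interval),
#'   `n_beats`, and `method`.
#' @export
beat_frequency <- function(events, duration) {
  if (duration <= 0) stop("`duration` must be positive")
  n <- length(events$peak_times)
  f_count <- n / duration
  f_int <- if (n >= 2) 1 / stats::median(diff(events$peak_times)) else NA_real_
  structure(list(frequency = f_count, frequency_interval = f_int,
                 n_beats = n, method = "count_over_duration"),
            class = "frequency_estimate")
}

#' Per-region analysis of a multi-focus recording
#'
#' Runs segmentation, area tracing, beat detection and frequency
#' estimation independently within each region of interest, e.g. for a
#' field of view containing two independently beating areas.
#'
#' @param stack a [frame_stack()].
#' @param roi_masks list of logical H x W matrices; must be pairwise
#'   disjoint and non-empty.
#' @param ... passed on to [detect_beats()].
#' @return list (one element per ROI) of lists with `trace`, `events`,
#'   `frequency`.
#' @export
analyze_rois <- function(stack, roi_masks, ...) {
  stopifnot(inherits(stack, "frame_stack"))
  if (!length(roi_masks)) stop("no ROIs given")
  for (m in roi_masks) {
    if (!is.logical(m) || !all(dim(m) == dim(stack$frames)[1:2]))
      stop("each ROI must be a logical matrix matching the frame size")
    if (!any(m)) stop("empty ROI")
  }
  if (length(roi_masks) > 1L) {
    acc <- matrix(0L, nrow(roi_masks[[1]]), ncol(roi_masks[[1]]))
    for (m in roi_masks) acc <- acc + m
    if (any(acc > 1L)) stop("ROIs overlap")
  }
  duration <- n_frames(stack) / stack$frame_rate
  lapply(roi_masks, function(m) {
    masks <- segment_stack(stack, roi = m)
    tr <- area_trace(masks, stack)
    ev <- detect_beats(tr, ...)
    list(trace = tr, events = ev, frequency = beat_frequency(ev, duration))
  })
}
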