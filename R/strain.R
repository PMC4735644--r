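# Strain channel: velocity-gradient tensor on the interrogation grid,
# contraction-positive scalar strain rate, spatially averaged strain
# trace, and the cumulative-strain / strain-per-beat metrics.

# Gradient along one matrix dimension with central differences inside
# and one-sided differences at the edges (exact for linear fields).
grad_dim <- function(m, spacing, along = c("col", "row")) {
  along <- match.arg(along)
  if (along == "row") return(t(grad_dim(t(m), spacing, "col")))
  nc <- ncol(m)
  if (nc < 2L) stop("need at least a 2 x 2 grid for gradients")
  g <- m
  g[, 2:(nc - 1)] <- (m[, 3:nc, drop = FALSE] - m[, 1:(nc - 2), drop = FALSE]) /
    (2 * spacing)
  g[, 1] <- (m[, 2] - m[, 1]) / spacing
  g[, nc] <- (m[, nc] - m[, nc - 1]) / spacing
  g
}

#' Scalar strain rate from a velocity field
#'
#' Computes the velocity-gradient components by central differences on
#' the interrogation grid and the contraction-positive scalar strain
#' rate `-(du/dx + dv/dy) / frame_interval`: the negative divergence,
#' positive while tissue converges (contracts). The sign convention is
#' exposed via `sign_convention`.
#'
#' @param field a `velocity_field` (u, v in px/frame).
#' @param frame_interval seconds between the two frames.
#' @param sign_convention `"contraction_positive"` (default) or
#'   `"divergence"` (raw divergence, expansion-positive).
#' @return a `strain_rate_field`: list with the grid, `scalar` (1/s),
#'   and the gradient tensor components `dudx`, `dudy`, `dvdx`, `dvdy`
#'   (1/s).
#' @export
velocity_to_strain_rate <- function(field, frame_interval,
                                    sign_convention = c("contraction_positive",
                                                        "divergence")) {
  sign_convention <- match.arg(sign_convention)
  stopifnot(inherits(field, "velocity_field"))
  if (frame_interval <= 0) stop("`frame_interval` must be positive")
  if (length(field$grid_x) < 2L || length(field$grid_y) < 2L)
    stop("degenerate interrogation grid; need at least 2 x 2 vectors")
  dx <- field$grid_x[2] - field$grid_x[1]
  dy <- field$grid_y[2] - field$grid_y[1]
  dudx <- grad_dim(field$u, dx, "col") / frame_interval
  dudy <- grad_dim(field$u, dy, "row") / frame_interval
  dvdx <- grad_dim(field$v, dx, "col") / frame_interval
  dvdy <- grad_dim(field$v, dy, "row") / frame_interval
  div <- dudx + dvdy
  scalar <- if (sign_convention == "contraction_positive") -div else div
  structure(list(grid_x = field$grid_x, grid_y = field$grid_y,
                 scalar = scalar, dudx = dudx, dudy = dudy,
                 dvdx = dvdx, dvdy = dvdy,
                 sign_convention = sign_convention),
            class = "strain_rate_field")
}

#' Spatially averaged strain-rate trace
#'
#' Averages the scalar strain rate over the (masked) beating area for
#' each frame pair, producing a 1-D trace of length `T - 1`.
#'
#' @param fields list of `strain_rate_field`s (one per frame pair), all
#'   on the same grid.
#' @param frame_interval seconds between frames.
#' @param mask optional logical image-sized matrix; only grid points
#'   whose centre lies inside contribute.
#' @return a data.frame (`strain_trace`) with `time_s` (midpoint of each
#'   frame pair) and `mean_strain_rate` (1/s).
#' @export
strain_trace <- function(fields, frame_interval, mask = NULL) {
  if (!length(fields)) stop("no strain-rate fields given")
  g1 <- fields[[1]]
  sel <- NULL
  if (!is.null(mask)) {
    sel <- matrix(mask[cbind(rep(g1$grid_y, times = length(g1$grid_x)),
                             rep(g1$grid_x, each = length(g1$grid_y)))],
                  length(g1$grid_y), length(g1$grid_x))
    if (!any(sel)) stop("mask excludes every interrogation point")
  }
  vals <- vapply(fields, function(f) {
    if (!all(f$grid_x == g1$grid_x) || !all(f$grid_y == g1$grid_y))
      stop("strain-rate fields are on inconsistent grids")
    s <- f$scalar
    if (!is.null(sel)) s <- s[sel]
    mean(s, na.rm = TRUE)
  }, numeric(1))
  out <- data.frame(time_s = (seq_along(fields) - 0.5) * frame_interval,
                    mean_strain_rate = vals)
  attr(out, "frame_interval") <- frame_interval
  class(out) <- c("strain_trace", "data.frame")
  out
}

#' Cumulative strain and strain per beat
#'
#' The cumulative strain is the time-integral of the positive part of
#' the mean strain rate (`sum(max(rate, 0)) * frame_interval`,
#' dimensionless); the strain per beat divides it by the number of
#' contractions. With zero beats the per-beat value is `NA` and the
#' cumulative strain is still returned.
#'
#' @param trace a [strain_trace()].
#' @param events optional `beat_events` from [detect_beats()] (used for
#'   the beat count); alternatively pass `n_beats` directly.
#' @param n_beats number of contractions, if `events` is not supplied.
#' @return a `contraction_metrics` list with `cumulative_strain`,
#'   `strain_per_beat` and `n_beats`.
#' @export
contraction_metrics <- function(trace, events = NULL, n_beats = NULL) {
  dt <- attr(trace, "frame_interval")
  if (is.null(dt)) dt <- stats::median(diff(trace$time_s))
  if (!is.null(events)) n_beats <- length(events$peak_times)
  if (is.null(n_beats)) stop("supply `events` or `n_beats`")
  cum <- sum(pmax(trace$mean_strain_rate, 0)) * dt
  structure(list(cumulative_strain = cum,
                 strain_per_beat = if (n_beats > 0) cum / n_beats else NA_real_,
                 n_beats = n_beats),
            class = "contraction_metrics")
}

#' Fixed-scale contraction-velocity heat map
#'
#' Converts a displacement field to speed in micrometres per second and
#' clips it to fixed colour limits (default 0-28 um/s) so that maps from
#' different recordings are directly comparable.
#'
#' @param field a `velocity_field` (u, v in px/frame).
#' @param pixel_size micrometres per pixel.
#' @param frame_interval seconds between frames.
#' @param colour_limits c(min, max) speed limits in um/s.
#' @param png_path optional path; when given, a PNG of the map is
#'   written there.
#' @return a `velocity_heatmap` list with `speed` (um/s, clipped),
#'   `colour_limits`, `clip_fraction` (fraction of finite pixels at or
#'   above the upper limit before clipping) and the grid.
#' @export
render_velocity_heatmap <- function(field, pixel_size, frame_interval,
                                    colour_limits = c(0, 28),
                                    png_path = NULL) {
  stopifnot(inherits(field, "velocity_field"))
  if (missing(pixel_size) || missing(frame_interval) ||
      is.null(pixel_size) || is.null(frame_interval))
    stop("physical units required: supply `pixel_size` and `frame_interval`")
  speed <- sqrt(field$u^2 + field$v^2) * pixel_size / frame_interval
  fin <- is.finite(speed)
  clip_fraction <- if (any(fin)) mean(speed[fin] >= colour_limits[2]) else NA_real_
  speed_clipped <- pmin(pmax(speed, colour_limits[1]), colour_limits[2])
  out <- structure(list(speed = speed_clipped,
                        colour_limits = colour_limits,
                        clip_fraction = clip_fraction,
                        grid_x = field$grid_x, grid_y = field$grid_y),
                   class = "velocity_heatmap")
  if (!is.null(png_path)) {
    grDevices::png(png_path, width = 480, height = 480)
    plot(out)
    grDevices::dev.off()
  }
  out
}

#' @export
plot.velocity_heatmap <- function(x, ...) {
  z <- t(x$speed)[, rev(seq_len(nrow(x$speed))), drop = FALSE]
  z[!is.finite(z)] <- x$colour_limits[1]
  graphics::image(x$grid_x, rev(x$grid_y), z, zlim = x$colour_limits,
                  col = grDevices::hcl.colors(64, "viridis"),
                  xlab = "x (px)", ylab = "y (px)",
                  main = sprintf("speed, %g-%g um/s",
                                 x$colour_limits[1], x$colour_limits[2]), ...)
  invisible(x)
}
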