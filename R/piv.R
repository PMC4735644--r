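# Particle image velocimetry: multi-pass FFT cross-correlation of
# interrogation windows between adjacent frames, with 3-point Gaussian
# subpixel peak fitting, peak-ratio/median-outlier vector validation and
# local-median replacement. Later passes re-use the previous pass as
# integer window offsets (offset-only multi-pass, no window deformation).

#' Define a multi-pass interrogation plan
#'
#' @param pass_sizes interrogation window sizes in px, strictly
#'   decreasing; default `c(64, 32, 16)` (three sequential passes).
#' @param overlap_fraction window overlap between neighbouring
#'   interrogation areas, in \[0, 0.75\].
#' @param mask optional logical image-sized matrix; vectors whose window
#'   centre falls outside are flagged invalid.
#' @param peak_ratio_min primary-to-secondary correlation peak ratio
#'   below which a vector is rejected.
#' @param mad_k global outlier rejection: vectors farther than
#'   `mad_k` scaled median absolute deviations from the median vector
#'   are rejected.
#' @return an `interrogation_plan` list.
#' @export
interrogation_plan <- function(pass_sizes = c(64, 32, 16),
                               overlap_fraction = 0.5, mask = NULL,
                               peak_ratio_min = 1.3, mad_k = 5) {
  pass_sizes <- as.integer(pass_sizes)
  if (any(diff(pass_sizes) >= 0)) stop("`pass_sizes` must be strictly decreasing")
  if (any(pass_sizes < 8L)) stop("interrogation windows below 8 px are unreliable")
  if (overlap_fraction < 0 || overlap_fraction > 0.75)
    stop("`overlap_fraction` must be in [0, 0.75]")
  structure(list(pass_sizes = pass_sizes, overlap_fraction = overlap_fraction,
                 mask = mask, peak_ratio_min = peak_ratio_min, mad_k = mad_k),
            class = "interrogation_plan")
}

# Full cross-correlation C(s) = sum_x a(x) b(x + s) of two equal-size
# windows via zero-padded FFT; returns the map for lags -L..L each axis,
# normalized by the per-lag overlap area (otherwise the implicit
# triangular taper biases the subpixel peak fit toward integer lags).
window_xcorr <- function(a, b, L) {
  w <- nrow(a)
  p <- 2L * w
  A <- matrix(0, p, p); A[1:w, 1:w] <- a
  B <- matrix(0, p, p); B[1:w, 1:w] <- b
  cc <- Re(stats::fft(Conj(stats::fft(A)) * stats::fft(B), inverse = TRUE)) / (p * p)
  # index for lag s (s in -L..L): ((s mod p) + 1)
  idx <- function(s) ((s %% p) + 1L)
  cc <- cc[idx(-L:L), idx(-L:L), drop = FALSE]
  overlap <- outer(w - abs(-L:L), w - abs(-L:L)) / (w * w)
  cc / overlap
}

# 3-point Gaussian subpixel refinement along one axis; parabolic
# fallback when a neighbour is non-positive (log undefined).
subpixel_offset <- function(cm, c0, cp) {
  if (c0 > 0 && cm > 0 && cp > 0) {
    denom <- 2 * (log(cm) + log(cp) - 2 * log(c0))
    if (denom < 0) return((log(cm) - log(cp)) / denom)
  }
  denom <- 2 * (cm + cp - 2 * c0)
  if (denom < 0) return((cm - cp) / denom)
  0
}

# Correlate one window pair; returns c(u, v, ratio) or NA on failure.
correlate_windows <- function(wa, wb, L) {
  wa <- wa - mean(wa); wb <- wb - mean(wb)
  sa <- sqrt(sum(wa^2)); sb <- sqrt(sum(wb^2))
  if (sa == 0 || sb == 0) return(c(0, 0, Inf))  # featureless: no motion signal
  cc <- window_xcorr(wa, wb, L) / (sa * sb)
  n <- 2L * L + 1L
  pk <- arrayInd(which.max(cc), dim(cc))
  if (pk[1] <= 1L || pk[1] >= n || pk[2] <= 1L || pk[2] >= n)
    return(c(NA_real_, NA_real_, NA_real_))  # peak on search boundary
  p1 <- cc[pk[1], pk[2]]
  # secondary peak outside the 3x3 neighbourhood of the primary
  cc2 <- cc
  cc2[max(1L, pk[1] - 1L):min(n, pk[1] + 1L),
      max(1L, pk[2] - 1L):min(n, pk[2] + 1L)] <- -Inf
  p2 <- max(cc2)
  ratio <- if (p2 > 0) p1 / p2 else Inf
  dv <- subpixel_offset(cc[pk[1] - 1L, pk[2]], p1, cc[pk[1] + 1L, pk[2]])
  du <- subpixel_offset(cc[pk[1], pk[2] - 1L], p1, cc[pk[1], pk[2] + 1L])
  u <- (pk[2] - L - 1L) + du
  v <- (pk[1] - L - 1L) + dv
  c(u, v, ratio)
}

# Constant-extrapolating bilinear interpolation of a grid field at
# arbitrary pixel positions.
interp_grid <- function(m, grid_y, grid_x, r, c) {
  ir <- if (length(grid_y) > 1L)
    1 + (r - grid_y[1]) / (grid_y[2] - grid_y[1]) else rep(1, length(r))
  ic <- if (length(grid_x) > 1L)
    1 + (c - grid_x[1]) / (grid_x[2] - grid_x[1]) else rep(1, length(c))
  ir <- pmin(pmax(ir, 1), nrow(m))
  ic <- pmin(pmax(ic, 1), ncol(m))
  bilinear_sample(m, ir, ic)
}

# Replace a vector by the median of its valid 3x3 grid neighbours.
local_median_fill <- function(m, valid) {
  out <- m
  bad <- which(!valid, arr.ind = TRUE)
  if (!nrow(bad)) return(out)
  glob <- stats::median(m[valid])
  for (i in seq_len(nrow(bad))) {
    r <- bad[i, 1]; c <- bad[i, 2]
    rs <- max(1L, r - 1L):min(nrow(m), r + 1L)
    cs <- max(1L, c - 1L):min(ncol(m), c + 1L)
    nb <- m[rs, cs][valid[rs, cs]]
    out[r, c] <- if (length(nb)) stats::median(nb) else glob
  }
  out
}

#' Frame-pair displacement field by multi-pass cross-correlation
#'
#' Estimates, on an interrogation grid, the displacement of image
#' texture from `frame_a` to `frame_b`. Windows are zero-meaned and the
#' correlation is coefficient-normalized; the integer peak is refined by
#' a 3-point Gaussian fit per axis. Vectors failing the peak-ratio test
#' or the global median-absolute-deviation filter are flagged invalid
#' and replaced by the local 3 x 3 median.
#'
#' @param frame_a,frame_b equal-sized numeric matrices.
#' @param plan an [interrogation_plan()].
#' @return a `velocity_field`: list with `grid_x`, `grid_y` (window
#'   centre coordinates, px), `u`, `v` (displacement in px/frame; u along
#'   columns/x, v along rows/y), `valid` (logical matrix; FALSE marks
#'   replaced or masked vectors) and `window` (final pass size).
#' @export
compute_displacement <- function(frame_a, frame_b,
                                 plan = interrogation_plan()) {
  stopifnot(inherits(plan, "interrogation_plan"))
  if (!all(dim(frame_a) == dim(frame_b))) stop("frames differ in size")
  H <- nrow(frame_a); W <- ncol(frame_a)
  if (max(plan$pass_sizes) > min(H, W))
    stop("interrogation window larger than the image")

  prev <- NULL
  for (w in plan$pass_sizes) {
    stride <- max(4L, as.integer(round(w * (1 - plan$overlap_fraction))))
    half <- w %/% 2L
    gy <- seq.int(half, H - half, by = stride)
    gx <- seq.int(half, W - half, by = stride)
    nr <- length(gy); nc <- length(gx)
    U <- matrix(0, nr, nc); V <- matrix(0, nr, nc)
    valid <- matrix(TRUE, nr, nc)
    L <- max(3L, w %/% 4L)
    for (ri in seq_len(nr)) {
      for (ci in seq_len(nc)) {
        cy <- gy[ri]; cx <- gx[ci]
        pu <- 0; pv <- 0
        if (!is.null(prev)) {
          pu <- round(interp_grid(prev$u, prev$gy, prev$gx, cy, cx))
          pv <- round(interp_grid(prev$v, prev$gy, prev$gx, cy, cx))
        }
        # clamp the offset window of frame B inside the image
        pv <- min(max(pv, half - cy), H - half - cy)
        pu <- min(max(pu, half - cx), W - half - cx)
        ra <- (cy - half + 1L):(cy + half)
        ca <- (cx - half + 1L):(cx + half)
        wa <- frame_a[ra, ca]
        wb <- frame_b[ra + pv, ca + pu]
        res <- correlate_windows(wa, wb, L)
        if (!all(is.finite(res[1:2])) || res[3] < plan$peak_ratio_min) {
          valid[ri, ci] <- FALSE
          U[ri, ci] <- NA_real_; V[ri, ci] <- NA_real_
        } else {
          U[ri, ci] <- pu + res[1]
          V[ri, ci] <- pv + res[2]
        }
      }
    }
    # global MAD outlier filter
    if (sum(valid) >= 4L) {
      mu <- stats::median(U[valid]); mv <- stats::median(V[valid])
      su <- stats::mad(U[valid]); sv <- stats::mad(V[valid])
      tol_u <- max(plan$mad_k * su, 0.2)
      tol_v <- max(plan$mad_k * sv, 0.2)
      out <- valid & (abs(U - mu) > tol_u | abs(V - mv) > tol_v)
      valid[out] <- FALSE
      U[out] <- NA_real_; V[out] <- NA_real_
    }
    if (any(valid)) {
      U <- local_median_fill(U, valid)
      V <- local_median_fill(V, valid)
    } else {
      U[] <- 0; V[] <- 0
    }
    prev <- list(u = U, v = V, gy = gy, gx = gx, valid = valid, window = w)
  }

  valid <- prev$valid
  if (!is.null(plan$mask)) {
    inside <- plan$mask[cbind(rep(prev$gy, times = length(prev$gx)),
                              rep(prev$gx, each = length(prev$gy)))]
    inside <- matrix(inside, length(prev$gy), length(prev$gx))
    valid <- valid & inside
    prev$u[!inside] <- NA_real_
    prev$v[!inside] <- NA_real_
  }
  structure(list(grid_x = prev$gx, grid_y = prev$gy,
                 u = prev$u, v = prev$v, valid = valid,
                 window = prev$window),
            class = "velocity_field")
}

#' Build a velocity field from explicit components
#'
#' Mostly used for analytic fixtures (e.g. affine flows) when testing
#' the strain-rate operators.
#'
#' @param grid_x,grid_y window-centre coordinates (px).
#' @param u,v displacement matrices (px/frame), dimension
#'   `length(grid_y)` x `length(grid_x)`.
#' @return a `velocity_field`.
#' @export
velocity_field <- function(grid_x, grid_y, u, v) {
  stopifnot(all(dim(u) == c(length(grid_y), length(grid_x))),
            all(dim(v) == dim(u)))
  structure(list(grid_x = grid_x, grid_y = grid_y, u = u, v = v,
                 valid = matrix(TRUE, nrow(u), ncol(u)), window = NA),
            class = "velocity_field")
}

#' Apply multi-pass PIV to every adjacent frame pair of a stack
#'
#' @param stack a [frame_stack()].
#' @param plan an [interrogation_plan()].
#' @return list of `velocity_field`s, length `n_frames(stack) - 1`.
#' @export
piv_stack <- function(stack, plan = interrogation_plan()) {
  stopifnot(inherits(stack, "frame_stack"))
  n <- n_frames(stack)
  lapply(seq_len(n - 1L), function(i)
    compute_displacement(stack$frames[, , i], stack$frames[, , i + 1L], plan))
}
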