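# Internal numeric helpers shared across analysis channels.

#' Centered moving average
#'
#' Smooths a numeric vector with a centred box filter. Edges use the
#' partial window so the output has the same length as the input and no
#' NA padding.
#'
#' @param x numeric vector.
#' @param width window width in samples; values < 2 return `x` unchanged.
#' @return numeric vector, same length as `x`.
#' @keywords internal
moving_average <- function(x, width) {
  width <- as.integer(round(width))
  n <- length(x)
  if (width < 2L || n < 2L) return(x)
  if (width > n) width <- n
  half <- (width - 1L) %/% 2L
  # cumulative-sum trick with partial windows at the edges
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + (width - 1L - half), n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Otsu threshold of a grayscale image
#'
#' Histogram-based two-class variance maximisation on 256 bins spanning
#' the observed intensity range. Invariant under positive affine
#' rescaling of the intensities.
#'
#' @param x numeric vector or matrix of intensities.
#' @param n_bins histogram resolution.
#' @return scalar threshold on the original intensity scale.
#' @keywords internal
otsu_threshold <- function(x, n_bins = 256L) {
  v <- as.numeric(x)
  v <- v[is.finite(v)]
  rng <- range(v)
  if (diff(rng) <= 0) return(rng[1])
  brk <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  h <- tabulate(findInterval(v, brk, rightmost.closed = TRUE), n_bins)
  p <- h / sum(h)
  mids <- (brk[-1] + brk[-length(brk)]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[n_bins]
  between <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  between[!is.finite(between)] <- -Inf
  # the maximum is a plateau across the empty gap between modes; take its
  # midpoint rather than its edge
  top <- which(between >= max(between) - 1e-12 * abs(max(between)))
  mean(mids[range(top)])
}

#' Bilinear interpolation on a matrix
#'
#' Samples matrix `m` at fractional (row, col) positions. Out-of-range
#' positions return `fill`.
#'
#' @param m numeric matrix.
#' @param r,c numeric vectors of row/column sample positions (1-based).
#' @param fill value for samples outside the matrix.
#' @return numeric vector of sampled values.
#' @keywords internal
bilinear_sample <- function(m, r, c, fill = 0) {
  nr <- nrow(m); nc <- ncol(m)
  out <- rep(fill, length(r))
  ok <- r >= 1 & r <= nr & c >= 1 & c <= nc & is.finite(r) & is.finite(c)
  if (!any(ok)) return(out)
  r <- r[ok]; c <- c[ok]
  r0 <- pmin(floor(r), nr - 1L); c0 <- pmin(floor(c), nc - 1L)
  fr <- r - r0; fc <- c - c0
  i00 <- r0 + (c0 - 1) * nr
  v <- m[i00] * (1 - fr) * (1 - fc) +
    m[i00 + 1] * fr * (1 - fc) +
    m[i00 + nr] * (1 - fr) * fc +
    m[i00 + nr + 1] * fr * fc
  out[ok] <- v
  out
}

#' Evaluate an expression with a temporary RNG seed
#'
#' Sets the seed for the duration of `expr` and restores the caller's
#' RNG state afterwards, so seeded generators do not perturb user code.
#'
#' @param seed integer seed or NULL (no seeding).
#' @param expr expression to evaluate.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Interpolated level crossings of a sampled signal
#'
#' Finds times where a uniformly sampled signal crosses `level`, with
#' linear interpolation between samples.
#'
#' @param t time vector (uniform).
#' @param y signal values.
#' @param level crossing level.
#' @param direction "up" (y rises through level), "down", or "both".
#' @return numeric vector of crossing times (possibly empty).
#' @keywords internal
level_crossings <- function(t, y, level, direction = c("both", "up", "down")) {
  direction <- match.arg(direction)
  d <- y - level
  s <- sign(d)
  idx <- which(s[-length(s)] * s[-1] < 0 | (s[-length(s)] != 0 & s[-1] == 0))
  if (direction == "up") idx <- idx[d[idx] < 0]
  if (direction == "down") idx <- idx[d[idx] > 0]
  if (!length(idx)) return(numeric(0))
  frac <- d[idx] / (d[idx] - d[idx + 1L])
  t[idx] + frac * (t[idx + 1L] - t[idx])
}

#' Standard error of the mean
#' @param x numeric vector.
#' @keywords internal
sem <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 2L) return(NA_real_)
  stats::sd(x) / sqrt(length(x))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
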