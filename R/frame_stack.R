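# FrameStack container and plain-format I/O.

#' Create a frame stack
#'
#' A `frame_stack` holds an ordered series of grayscale frames with a
#' uniform frame interval. It is the raw substrate for the contractility,
#' PIV and calcium channels.
#'
#' @param frames numeric array of dimension H x W x T (intensities in any
#'   units; internally generators use \[0, 1\]).
#' @param frame_rate frames per second.
#' @param pixel_size optional micrometres per pixel; required only when a
#'   downstream stage reports physical units.
#' @return an object of class `frame_stack` with elements `frames`,
#'   `frame_interval` (s), `frame_rate`, `pixel_size` and `time` (s, one
#'   entry per frame, starting at 0).
#' @export
frame_stack <- function(frames, frame_rate, pixel_size = NULL) {
  if (length(dim(frames)) != 3L)
    stop("`frames` must be an H x W x T array")
  if (dim(frames)[3] < 2L)
    stop("a frame stack needs at least 2 frames")
  if (!is.numeric(frame_rate) || length(frame_rate) != 1L || frame_rate <= 0)
    stop("`frame_rate` must be a positive scalar")
  if (!all(is.finite(frames)))
    stop("frame intensities must be finite")
  structure(
    list(
      frames = frames,
      frame_rate = frame_rate,
      frame_interval = 1 / frame_rate,
      pixel_size = pixel_size,
      time = (seq_len(dim(frames)[3]) - 1) / frame_rate
    ),
    class = "frame_stack"
  )
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<frame_stack> %d frames of %d x %d px at %g fps (%.2f s)\n",
              d[3], d[1], d[2], x$frame_rate, d[3] / x$frame_rate))
  if (!is.null(x$pixel_size))
    cat(sprintf("  pixel size: %g um/px\n", x$pixel_size))
  invisible(x)
}

#' Number of frames in a stack
#' @param stack a [frame_stack()].
#' @return integer frame count.
#' @export
n_frames <- function(stack) dim(stack$frames)[3]

#' Write a frame stack to a multipage TIFF
#'
#' Intensities are clipped to \[0, 1\] and stored as 16-bit grayscale.
#'
#' @param stack a [frame_stack()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_frame_stack <- function(stack, path) {
  frames <- lapply(seq_len(n_frames(stack)), function(i) {
    f <- stack$frames[, , i]
    f[f < 0] <- 0
    f[f > 1] <- 1
    f
  })
  tiff::writeTIFF(frames, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a multipage TIFF into a frame stack
#'
#' @param path TIFF file path.
#' @param frame_rate frames per second of the recording.
#' @param pixel_size optional micrometres per pixel.
#' @return a [frame_stack()].
#' @export
read_frame_stack <- function(path, frame_rate, pixel_size = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) if (length(dim(p)) == 3L) p[, , 1] else p)
  frames <- array(unlist(pages), dim = c(dim(pages[[1]]), length(pages)))
  frame_stack(frames, frame_rate, pixel_size)
}

#' Write a two-column (time, value) trace to CSV
#'
#' @param time,value numeric vectors of equal length.
#' @param path output path.
#' @param value_name column name for the value column.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(time, value, path, value_name = "value") {
  df <- data.frame(time_s = time, value = value)
  names(df)[2] <- value_name
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a two-column (time, value) trace from CSV
#'
#' @param path CSV with time in the first column and the signal in the
#'   second.
#' @return data.frame with columns `time_s` and `value`.
#' @export
read_trace_csv <- function(path) {
  df <- utils::read.csv(path)
  if (ncol(df) < 2L) stop("trace CSV needs at least two columns")
  data.frame(time_s = df[[1]], value = df[[2]])
}
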