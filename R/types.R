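#' Construct an image frame
#'
#' A 2D grayscale raster with a physical pixel pitch, the common container for
#' simulated pupil-camera frames and summed-voxel projections. Pixels are
#' stored as a numeric matrix with rows indexing y (downward) and columns
#' indexing x (rightward); pixel centers sit at integer 0-based coordinates,
#' so the frame center is at `((ncol-1)/2, (nrow-1)/2)`.
#'
#' @param pixels numeric matrix of gray levels (rows = y, columns = x).
#' @param pixel_size physical pixel pitch in mm/pixel.
#' @param timestamp acquisition time in seconds.
#' @return An object of class `image_frame`.
#' @export
image_frame <- function(pixels, pixel_size, timestamp = 0) {
  if (!is.matrix(pixels) || length(pixels) == 0L) {
    .pt_abort("'pixels' must be a non-empty matrix", "pupiltrack_invalid_parameter")
  }
  if (any(!is.finite(pixels))) {
    .pt_abort("'pixels' must be finite", "pupiltrack_invalid_parameter")
  }
  .check_positive(pixel_size, "pixel_size")
  structure(list(pixels = pixels, pixel_size = pixel_size, timestamp = timestamp),
            class = "image_frame")
}

#' @export
print.image_frame <- function(x, ...) {
  cat(sprintf("<image_frame> %d x %d px, %.4g mm/px, t = %.4g s\n",
              ncol(x$pixels), nrow(x$pixels), x$pixel_size, x$timestamp))
  invisible(x)
}

#' @export
dim.image_frame <- function(x) dim(x$pixels)

#' Construct a motion trace
#'
#' Time-indexed lateral displacement series, the common currency of input
#' trajectories, tracker output, correction waveforms and edge traces.
#'
#' @param t time stamps in seconds; must be uniformly spaced and increasing.
#' @param x,y lateral displacement per sample, in mm (or lateral samples for
#'   raw edge traces; see `units`).
#' @param units unit of the displacement columns, `"mm"` or `"samples"`.
#' @return A `data.frame` of class `motion_trace` with columns `t`, `x`, `y`
#'   and attributes `rate` (sampling rate, Hz) and `units`.
#' @export
motion_trace <- function(t, x, y = 0, units = "mm") {
  n <- length(t)
  if (n < 1L) .pt_abort("empty trace", "pupiltrack_invalid_parameter")
  x <- rep_len(x, n)
  y <- rep_len(y, n)
  if (any(!is.finite(t)) || any(!is.finite(x)) || any(!is.finite(y))) {
    .pt_abort("motion trace values must be finite", "pupiltrack_invalid_parameter")
  }
  if (n > 1L) {
    dt <- diff(t)
    if (any(dt <= 0)) .pt_abort("'t' must be strictly increasing", "pupiltrack_invalid_parameter")
    if (diff(range(dt)) > 1e-6 * mean(dt)) {
      .pt_abort("'t' must be uniformly sampled", "pupiltrack_invalid_parameter")
    }
    rate <- 1 / mean(dt)
  } else {
    rate <- NA_real_
  }
  structure(data.frame(t = t, x = x, y = y),
            rate = rate, units = units,
            class = c("motion_trace", "data.frame"))
}

#' Sampling rate of a motion trace
#' @param trace a [motion_trace()].
#' @return Sampling rate in Hz.
#' @export
trace_rate <- function(trace) {
  r <- attr(trace, "rate")
  if (is.null(r) || is.na(r)) {
    if (nrow(trace) > 1L) r <- 1 / mean(diff(trace$t)) else r <- NA_real_
  }
  r
}

#' Construct a transfer function
#'
#' Frequency grid with magnitude values, normalized so the DC magnitude is 1,
#' plus the location of the first -3 dB crossing.
#'
#' @param frequencies strictly increasing frequency grid in Hz.
#' @param magnitude non-negative magnitudes, one per frequency.
#' @param rolloff_3db frequency of the first -3 dB crossing in Hz, or
#'   `NA_real_` when the magnitude never falls that far ("not reached").
#' @return An object of class `transfer_function`.
#' @export
transfer_function <- function(frequencies, magnitude, rolloff_3db = NA_real_) {
  if (length(frequencies) != length(magnitude)) {
    .pt_abort("'frequencies' and 'magnitude' must have equal length",
              "pupiltrack_invalid_parameter")
  }
  if (any(diff(frequencies) <= 0)) {
    .pt_abort("'frequencies' must be strictly increasing", "pupiltrack_invalid_parameter")
  }
  if (any(!is.finite(magnitude)) || any(magnitude < 0)) {
    .pt_abort("'magnitude' must be finite and non-negative", "pupiltrack_invalid_parameter")
  }
  structure(list(frequencies = frequencies, magnitude = magnitude,
                 rolloff_3db = rolloff_3db),
            class = "transfer_function")
}

#' @export
print.transfer_function <- function(x, ...) {
  ro <- if (is.na(x$rolloff_3db)) "not reached" else sprintf("%.3g Hz", x$rolloff_3db)
  cat(sprintf("<transfer_function> %d frequencies in [%.3g, %.3g] Hz, -3 dB roll-off: %s\n",
              length(x$frequencies), min(x$frequencies), max(x$frequencies), ro))
  invisible(x)
}
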