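#' Analytic residual amplitude under loop latency
#'
#' Models subject motion as `x(t) = A sin(2 pi f t)` and the tracking output
#' as the inverted, delayed copy `y(t) = -A sin(2 pi f (t + dt))`. Their sum,
#' the motion left uncorrected, factors into
#' `x(t) + y(t) = -2 A sin(pi f dt) cos(pi f (2 t + dt))`, an oscillation
#' whose envelope amplitude is `2 A |sin(pi f dt)|`. Residual values above
#' `A` (ratio > 1) mark the amplification regime, where latency makes
#' tracking worse than no tracking.
#'
#' @param A subject motion amplitude, mm.
#' @param f motion frequency, Hz.
#' @param dt loop latency Delta-t, seconds.
#' @return Residual motion amplitude `2 A |sin(pi f dt)|` in mm (vectorized
#'   over `f` and `dt`).
#' @examples
#' residual_amplitude(1, 20, 0.004) # ~0.50: half the input at 20 Hz for 4 ms
#' @export
residual_amplitude <- function(A = 1, f, dt) {
  if (any(A < 0) || any(f < 0) || any(dt < 0)) {
    .pt_abort("'A', 'f' and 'dt' must be non-negative", "pupiltrack_invalid_parameter")
  }
  2 * A * abs(sin(pi * f * dt))
}

#' Check the residual sum-to-product identity
#'
#' Evaluates both sides of the factorization of the uncorrected residual:
#' the explicit sum `A sin(2 pi f t) - A sin(2 pi f (t + dt))` and the
#' product form `-2 A sin(pi f dt) cos(pi f (2 t + dt))`. The two are equal
#' for all parameters (sum-to-product identity); the function returns both so
#' callers can verify.
#'
#' @param A amplitude, mm.
#' @param f frequency, Hz.
#' @param dt latency, seconds.
#' @param t evaluation time(s), seconds.
#' @return List with `lhs` (sum form) and `rhs` (product form).
#' @export
residual_identity_check <- function(A = 1, f, dt, t) {
  lhs <- A * sin(2 * pi * f * t) - A * sin(2 * pi * f * (t + dt))
  rhs <- -2 * A * sin(pi * f * dt) * cos(pi * f * (2 * t + dt))
  list(lhs = lhs, rhs = rhs)
}

#' Frequency at which the residual reaches half the input amplitude
#'
#' Solves `2 sin(pi f dt) = 0.5` for `f`, giving
#' `f = asin(0.25) / (pi dt)`: the motion frequency at which a loop with
#' latency `dt` leaves a residual of 50% of the subject motion amplitude.
#' This is the operational -3 dB point of the motion-correction transfer
#' function. For a 4 ms loop it evaluates to about 20 Hz.
#'
#' @param dt loop latency, seconds (> 0).
#' @return Frequency in Hz (vectorized over `dt`); monotone decreasing in
#'   `dt` and unbounded as `dt -> 0`.
#' @examples
#' half_amplitude_frequency(0.004) # ~20.1 Hz
#' @export
half_amplitude_frequency <- function(dt) {
  if (any(dt <= 0)) .pt_abort("'dt' must be positive", "pupiltrack_invalid_parameter")
  asin(0.25) / (pi * dt)
}

#' Normalized residual surface over latency and frequency
#'
#' Tabulates the normalized residual amplitude `2 |sin(pi f dt)|` over a grid
#' of latencies (rows) and motion frequencies (columns). Entries above 1 mark
#' the amplification regime; along each row the boundary `2 sin(pi f dt) = 1`
#' sits at `f = 1 / (6 dt)`.
#'
#' @param dt_range latency grid, seconds.
#' @param f_range frequency grid, Hz.
#' @return Matrix with `length(dt_range)` rows and `length(f_range)` columns;
#'   dimnames carry the axis values.
#' @export
residual_surface <- function(dt_range = seq(0, 0.010, by = 0.0005),
                             f_range = seq(0, 100, by = 1)) {
  if (length(dt_range) == 0L || length(f_range) == 0L) {
    .pt_abort("grids must be non-empty", "pupiltrack_invalid_parameter")
  }
  m <- outer(dt_range, f_range, function(dt, f) 2 * abs(sin(pi * f * dt)))
  dimnames(m) <- list(dt = format(dt_range, trim = TRUE),
                      f = format(f_range, trim = TRUE))
  m
}

#' Export a residual surface as CSV
#'
#' Writes the matrix from [residual_surface()] with latency/frequency axis
#' headers: first column `dt_s`, remaining columns named by frequency.
#'
#' @param surface matrix from [residual_surface()].
#' @param path output CSV path.
#' @return The path, invisibly.
#' @export
write_residual_surface <- function(surface, path) {
  df <- data.frame(dt_s = rownames(surface), surface, check.names = FALSE)
  names(df)[-1] <- paste0("f_", colnames(surface), "_Hz")
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
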