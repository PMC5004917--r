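#' Generate a deterministic test trajectory
#'
#' Canonical waveforms used to drive the simulated phantom: a step (0 before
#' `duration/2`, `amplitude` after), a sinusoid `amplitude * sin(2 pi f t)`,
#' or a constant zero trace. Motion is along x; y is zero.
#'
#' @param kind `"step"`, `"sinusoid"` or `"constant"`.
#' @param amplitude displacement amplitude in mm.
#' @param frequency sinusoid frequency in Hz (ignored for step/constant).
#' @param duration trace duration in seconds.
#' @param rate sampling rate in Hz; must exceed twice the frequency for
#'   sinusoids.
#' @return A [motion_trace()] with `round(duration * rate)` samples.
#' @examples
#' tr <- generate_trajectory("sinusoid", amplitude = 1, frequency = 1,
#'                           duration = 2, rate = 1000)
#' tr$x[tr$t == 0.25]  # peak of the sine
#' @export
generate_trajectory <- function(kind = c("step", "sinusoid", "constant"),
                                amplitude = 1, frequency = 1,
                                duration, rate) {
  kind <- match.arg(kind)
  .check_positive(duration, "duration")
  .check_positive(rate, "rate")
  if (kind == "sinusoid") {
    .check_positive(frequency, "frequency")
    if (rate <= 2 * frequency) {
      .pt_abort("'rate' must exceed twice 'frequency' for sinusoids",
                "pupiltrack_invalid_parameter")
    }
  }
  n <- round(duration * rate)
  t <- (0:(n - 1)) / rate
  x <- switch(kind,
              step = ifelse(t < duration / 2, 0, amplitude),
              sinusoid = amplitude * sin(2 * pi * frequency * t),
              constant = rep(0, n))
  motion_trace(t, x, 0)
}

# Colored (1/f^alpha) Gaussian noise via frequency-domain synthesis, unit
# scale, zero mean. Above `cutoff` the amplitude rolls off as (cutoff/f)^2
# (f^-4 in power), bounding the synthetic tremor band. Uses the current RNG
# stream.
.colored_noise <- function(n, rate, alpha, cutoff = Inf) {
  nf <- n %/% 2L
  f <- (1:nf) * rate / n
  amp <- f^(-alpha / 2) * ifelse(f <= cutoff, 1, (cutoff / f)^2)
  z <- complex(real = rnorm(nf), imaginary = rnorm(nf)) * amp
  spec <- complex(real = numeric(n))
  spec[2:(nf + 1L)] <- z
  if (n %% 2L == 0L) spec[nf + 1L] <- complex(real = rnorm(1) * amp[nf])
  for (k in 2:(nf + 1L)) spec[n - k + 2L] <- Conj(spec[k])
  Re(fft(spec, inverse = TRUE)) / n
}

#' Generate a fixational eye-motion trajectory
#'
#' Emulates involuntary fixational eye movements: a drift/tremor component
#' with power spectral density proportional to `1/f^psd_exponent`
#' (reported exponents for fixational motion lie between 1 and 2, with most
#' motion power below 10 Hz), plus Poisson-timed microsaccades modelled as
#' instantaneous steps in a random direction. The combined 2D displacement is
#' centered and scaled to the requested RMS. Deterministic for a fixed seed.
#'
#' Above `drift_bandwidth` the drift/tremor spectrum rolls off steeply
#' (f^-4 in power): physiological tremor beyond a few tens of Hz carries
#' sub-micron amplitude, and extending the 1/f law to the sampling Nyquist
#' would place drift-scale power at frequencies where no eye moves.
#'
#' @param duration trace duration in seconds. Default 10 s, a typical steady
#'   fixation epoch.
#' @param rate sampling rate in Hz (>= 100).
#' @param psd_exponent spectral slope of the drift/tremor component, in
#'   `[1, 2]`.
#' @param rms_amplitude target RMS of the 2D displacement magnitude, mm.
#'   Default 0.1 mm, the scale of lateral fixational excursions seen in
#'   anterior-segment imaging.
#' @param microsaccade_rate mean microsaccade rate, Hz (typically 1-2 per
#'   second; 0 disables them).
#' @param microsaccade_amplitude step size of each microsaccade in mm
#'   (applied before the global RMS rescaling).
#' @param drift_bandwidth corner frequency (Hz) above which the drift/tremor
#'   spectrum rolls off as f^-4 in power.
#' @param seed integer RNG seed, or `NULL` to use the current stream.
#' @return A [motion_trace()].
#' @export
generate_fixational_trajectory <- function(duration = 10, rate = 500,
                                           psd_exponent = 1,
                                           rms_amplitude = 0.1,
                                           microsaccade_rate = 1.5,
                                           microsaccade_amplitude = 0.1,
                                           drift_bandwidth = 50,
                                           seed = NULL) {
  .check_positive(duration, "duration")
  .check_positive(rate, "rate")
  if (rate < 100) {
    .pt_abort("'rate' must be at least 100 Hz", "pupiltrack_invalid_parameter")
  }
  if (psd_exponent < 1 || psd_exponent > 2) {
    .pt_abort("'psd_exponent' must lie in [1, 2]", "pupiltrack_invalid_parameter")
  }
  .check_nonneg(rms_amplitude, "rms_amplitude")
  .check_nonneg(microsaccade_rate, "microsaccade_rate")
  if (!is.null(seed)) set.seed(seed)
  n <- round(duration * rate)
  t <- (0:(n - 1)) / rate
  x <- .colored_noise(n, rate, psd_exponent, cutoff = drift_bandwidth)
  y <- .colored_noise(n, rate, psd_exponent, cutoff = drift_bandwidth)
  # normalize drift so microsaccade amplitude is commensurate with mm
  s <- sqrt(mean(x^2 + y^2))
  if (s > 0) {
    x <- x / s * rms_amplitude
    y <- y / s * rms_amplitude
  }
  if (microsaccade_rate > 0) {
    k <- rpois(1, microsaccade_rate * duration)
    if (k > 0) {
      times <- runif(k, 0, duration)
      angles <- runif(k, 0, 2 * pi)
      for (i in seq_len(k)) {
        step <- t >= times[i]
        x[step] <- x[step] + microsaccade_amplitude * cos(angles[i])
        y[step] <- y[step] + microsaccade_amplitude * sin(angles[i])
      }
    }
  }
  x <- x - mean(x); y <- y - mean(y)
  s <- sqrt(mean(x^2 + y^2))
  if (s > 0 && rms_amplitude > 0) {
    x <- x / s * rms_amplitude
    y <- y / s * rms_amplitude
  }
  motion_trace(t, x, y)
}
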