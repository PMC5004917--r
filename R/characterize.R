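#' Frequency response from a recorded step response
#'
#' Bench estimator for the tracking loop's bandwidth: the first difference of
#' the recorded step response approximates the impulse response, and the
#' magnitude of its discrete Fourier transform, normalized to DC = 1, gives
#' the frequency response. The -3 dB crossing is located by linear
#' interpolation between grid points. An optional first-order fit
#' `A (1 - exp(-(t - t0)/tau))` can be applied to the raw step before
#' differencing to suppress measurement noise.
#'
#' @param step a [motion_trace()] containing one rising step.
#' @param prefit `"none"` (difference the raw trace) or `"first_order"`
#'   (difference a fitted first-order step instead).
#' @return A [transfer_function()] covering DC to Nyquist.
#' @export
step_to_frequency_response <- function(step, prefit = c("none", "first_order")) {
  stopifnot(inherits(step, "motion_trace"))
  prefit <- match.arg(prefit)
  rate <- trace_rate(step)
  x <- step$x
  if (prefit == "first_order") {
    x <- .fit_first_order_step(step$t, x)
  }
  imp <- diff(x)
  n <- length(imp)
  if (all(imp == 0)) {
    .pt_abort("constant trace: impulse estimate is all zero", "pupiltrack_degenerate")
  }
  mag <- Mod(fft(imp))
  if (mag[1] == 0) {
    .pt_abort("step has zero net amplitude; cannot normalize to DC",
              "pupiltrack_degenerate")
  }
  mag <- mag / mag[1]
  nk <- floor(n / 2) + 1L
  freqs <- (0:(nk - 1)) * rate / n
  ro <- .first_crossing_below(freqs, mag[1:nk], 10^(-3 / 20))
  transfer_function(freqs, mag[1:nk], ro)
}

# Least-squares fit of a delayed first-order step A*(1-exp(-(t-t0)/tau)).
.fit_first_order_step <- function(t, x) {
  base <- mean(x[seq_len(max(1L, floor(length(x) * 0.1)))])
  amp0 <- max(x) - base
  t0_0 <- t[which(x - base > 0.1 * amp0)[1L]]
  if (is.na(t0_0)) t0_0 <- t[1]
  model <- function(p) {
    y <- p[1] * (1 - exp(-(t - p[2]) / p[3]))
    y[t < p[2]] <- 0
    base + y
  }
  obj <- function(p) if (p[3] <= 0) 1e12 else sum((x - model(p))^2)
  fit <- stats::optim(c(amp0, t0_0, diff(range(t)) / 20), obj)
  model(fit$par)
}

#' Estimate loop latency by cross-correlation
#'
#' The correction waveform of a proportional tracker is an inverted, delayed
#' copy of the drive; the lag maximizing the cross-correlation between the
#' drive and the negated response is read out as the loop latency. Resolution
#' is one sampling interval.
#'
#' @param drive drive waveform, a [motion_trace()].
#' @param response response waveform at the same sampling rate (sign as
#'   physically recorded, i.e. inverted relative to the drive).
#' @param max_lag largest lag searched, seconds.
#' @return Latency in seconds (non-negative lag of the best match).
#' @export
estimate_latency <- function(drive, response, max_lag = 0.1) {
  stopifnot(inherits(drive, "motion_trace"), inherits(response, "motion_trace"))
  rd <- trace_rate(drive); rr <- trace_rate(response)
  if (abs(rd - rr) > 1e-6 * rd) {
    .pt_abort("drive and response must share the sampling rate",
              "pupiltrack_invalid_parameter")
  }
  x <- drive$x - mean(drive$x)
  y <- -(response$x - mean(response$x))
  if (sd(x) == 0 || sd(y) == 0) {
    .pt_abort("zero-variance input: correlation undefined",
              "pupiltrack_undefined_correlation")
  }
  L <- min(round(max_lag * rd), length(x) - 2L)
  s <- .xcorr_shift(x, y, max_lag = L)
  s / rd
}

# Lag s maximizing the normalized cross-correlation such that b[i] ~ a[i-s]
# (positive s: b is a delayed/shifted copy of a). Optional parabolic
# refinement of the peak to sub-sample precision.
.xcorr_shift <- function(a, b, max_lag, refine = FALSE) {
  n <- length(a)
  a <- a - mean(a); b <- b - mean(b)
  if (all(a == 0) || all(b == 0)) {
    .pt_abort("featureless input: shift undefined", "pupiltrack_undefined_shift")
  }
  lags <- (-max_lag):max_lag
  cc <- vapply(lags, function(l) {
    if (l >= 0) {
      aa <- a[seq_len(n - l)]; bb <- b[(1 + l):n]
    } else {
      aa <- a[(1 - l):n]; bb <- b[seq_len(n + l)]
    }
    den <- sqrt(sum(aa^2) * sum(bb^2))
    if (den == 0) -Inf else sum(aa * bb) / den
  }, numeric(1))
  # ties (e.g. periodic content) resolve to the smallest displacement
  best <- which(cc >= max(cc) - 1e-12)
  i <- best[which.min(abs(lags[best]))]
  s <- lags[i]
  if (refine && i > 1L && i < length(lags) && is.finite(cc[i - 1]) && is.finite(cc[i + 1])) {
    denom <- cc[i - 1] - 2 * cc[i] + cc[i + 1]
    if (denom < 0) s <- s + 0.5 * (cc[i - 1] - cc[i + 1]) / denom
  }
  s
}

#' Extract a motion trace from a summed-voxel projection
#'
#' Reproduces the SVP edge-tracing pipeline used to characterize OCT motion
#' correction: the SVP (rows = B-scans over time, columns = lateral samples)
#' is smoothed with a 3 x 3 Gaussian kernel, intensity-thresholded to a
#' binary image, and Sobel edge detection locates the imaged pupil edge in
#' each row. Rows without a detectable edge are filled by linear
#' interpolation from neighboring rows and flagged.
#'
#' @param svp an [image_frame()] as returned by [svp()] (carries the B-scan
#'   rate); rows index B-scan time.
#' @param threshold binary threshold on the smoothed image; default is Otsu.
#' @param bscan_rate B-scan rate in Hz, taken from the `svp` attribute when
#'   present.
#' @param units `"samples"` (lateral samples) or `"mm"` (converted via the
#'   SVP's pixel pitch).
#' @return A [motion_trace()] of per-B-scan edge positions; the attribute
#'   `interpolated_rows` lists rows that had no edge.
#' @export
extract_edge_trace <- function(svp, threshold = NULL, bscan_rate = NULL,
                               units = c("samples", "mm")) {
  stopifnot(inherits(svp, "image_frame"))
  units <- match.arg(units)
  if (is.null(bscan_rate)) bscan_rate <- attr(svp, "bscan_rate")
  px <- svp$pixels
  n <- nrow(px); A <- ncol(px)
  g <- outer(c(1, 2, 1), c(1, 2, 1)); g <- g / sum(g)
  sm <- EBImage::filter2(px, g, boundary = "replicate")
  rng <- range(sm)
  if (is.null(threshold)) {
    if (diff(rng) == 0) {
      .pt_abort("featureless SVP: no edge to trace", "pupiltrack_undefined_shift")
    }
    norm <- (sm - rng[1]) / diff(rng)
    threshold <- rng[1] + EBImage::otsu(norm, range = c(0, 1), levels = 256) * diff(rng)
  }
  bin <- (sm > threshold) * 1
  sobel_x <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3) # column gradient
  gx <- EBImage::filter2(bin, sobel_x, boundary = "replicate")
  agx <- abs(gx)
  edge <- numeric(n)
  miss <- logical(n)
  for (k in seq_len(n)) {
    m <- max(agx[k, ])
    if (m <= 0) {
      miss[k] <- TRUE
      edge[k] <- NA_real_
    } else {
      edge[k] <- which.max(agx[k, ]) - 1 # 0-based lateral sample
    }
  }
  if (any(miss)) {
    if (all(miss)) {
      .pt_abort("no edge found in any row", "pupiltrack_undefined_shift")
    }
    ok <- which(!miss)
    edge[miss] <- approx(ok, edge[ok], xout = which(miss), rule = 2)$y
  }
  t <- if (!is.null(bscan_rate)) (0:(n - 1)) / bscan_rate else 0:(n - 1)
  x <- if (units == "mm") edge * svp$pixel_size else edge
  tr <- motion_trace(t, x, 0, units = units)
  attr(tr, "interpolated_rows") <- which(miss)
  tr
}

#' Motion-correction transfer function from amplitude ratios
#'
#' Builds the correction transfer function from per-frequency amplitudes of
#' the uncorrected and corrected motion traces. The residual ratio
#' `r(f) = corrected / uncorrected` gives the correction percentage
#' `1 - r(f)`; ratios above 1 (amplification, possible at high frequency
#' under latency) appear as negative correction percentages. The roll-off is
#' reported, by default, as the frequency where the residual ratio reaches
#' 0.5 -- the half-residual point that the analytic latency model ties to the
#' loop latency -- with a strict amplitude -3 dB criterion (residual ratio
#' reaching `10^(-3/20)`, about 0.708) available as an alternative.
#'
#' @param frequencies drive frequencies, Hz.
#' @param uncorrected_amps,corrected_amps trace amplitudes (same units) per
#'   frequency; uncorrected amplitudes must be positive.
#' @param criterion `"half_residual"` (r reaches 0.5, interpolated) or
#'   `"amplitude_3db"` (r reaches `10^(-3/20)`).
#' @return List of class `correction_tf`: `frequencies`, `residual_ratio`,
#'   `correction_pct`, `rolloff_3db` (Hz, `NA` if not reached within the
#'   grid) and `criterion`.
#' @export
correction_transfer_function <- function(frequencies, uncorrected_amps,
                                         corrected_amps,
                                         criterion = c("half_residual", "amplitude_3db")) {
  criterion <- match.arg(criterion)
  if (length(frequencies) != length(uncorrected_amps) ||
      length(frequencies) != length(corrected_amps)) {
    .pt_abort("frequency and amplitude lists must have equal length",
              "pupiltrack_invalid_parameter")
  }
  if (any(uncorrected_amps <= 0)) {
    .pt_abort("uncorrected amplitudes must be positive", "pupiltrack_invalid_parameter")
  }
  o <- order(frequencies)
  f <- frequencies[o]
  r <- (corrected_amps / uncorrected_amps)[o]
  pct <- 1 - r
  ro <- if (criterion == "half_residual") {
    .first_crossing_above(f, r, 0.5)
  } else {
    .first_crossing_above(f, r, 10^(-3 / 20))
  }
  structure(list(frequencies = f, residual_ratio = r, correction_pct = pct,
                 rolloff_3db = ro, criterion = criterion),
            class = "correction_tf")
}

#' @export
print.correction_tf <- function(x, ...) {
  ro <- if (is.na(x$rolloff_3db)) "not reached" else sprintf("%.3g Hz", x$rolloff_3db)
  cat(sprintf("<correction_tf> %d frequencies, criterion '%s', roll-off %s\n",
              length(x$frequencies), x$criterion, ro))
  invisible(x)
}

#' Measure the closed-loop correction response over a frequency sweep
#'
#' Drives the simulated loop with constant-amplitude sinusoidal phantom
#' motion at each frequency, estimates uncorrected and corrected amplitudes
#' at the drive frequency (DFT component over an integer number of periods
#' after the loop transient), and returns the per-frequency table.
#'
#' @param frequencies sweep frequencies, Hz.
#' @param scene,cal,loop scene, calibration and loop configuration.
#' @param amplitude drive amplitude, mm.
#' @param seed master RNG seed; each frequency uses a derived sub-seed.
#' @param settle transient discarded before amplitude estimation, seconds.
#' @param min_window minimum analysis window, seconds (extended to at least
#'   two drive periods).
#' @return `data.frame` with columns `frequency`, `uncorrected`, `corrected`.
#' @export
measure_correction_response <- function(frequencies, scene = scene_params(),
                                        cal = gain_calibration(),
                                        loop = loop_config(), amplitude = 1,
                                        seed = 1, settle = 0.2,
                                        min_window = 0.6) {
  if (length(frequencies) == 0L) {
    .pt_abort("'frequencies' must be non-empty", "pupiltrack_invalid_parameter")
  }
  seeds <- .sub_seeds(seed, length(frequencies))
  rows <- lapply(seq_along(frequencies), function(i) {
    f <- frequencies[i]
    np <- max(2, ceiling(min_window * f))
    dur <- settle + np / f + 2 / loop$camera_rate
    traj <- generate_trajectory("sinusoid", amplitude = amplitude,
                                frequency = f, duration = dur,
                                rate = max(2 * loop$camera_rate, 4 * f))
    sim <- simulate_closed_loop(traj, scene, cal, loop, seed = seeds[i])
    data.frame(frequency = f,
               uncorrected = trace_amplitude(sim$uncorrected, f, skip = settle),
               corrected = trace_amplitude(sim$corrected, f, skip = settle))
  })
  do.call(rbind, rows)
}

#' Optimize the adjustable loop gain
#'
#' Tunes `beta` by minimizing the residual motion of the closed-loop
#' simulation under sinusoidal drive at a probe frequency well inside the
#' correction band (0.5 Hz by default): a coarse grid over the search
#' interval brackets the minimum, then golden-section refinement
#' ([stats::optimize()]) polishes it. Every evaluation reuses the same seed,
#' so the objective is deterministic. A non-unimodal grid profile triggers a
#' warning and the global grid minimum is refined locally anyway.
#'
#' @param scene,cal,loop scene, calibration and loop configuration; `beta`
#'   inside `cal` is ignored.
#' @param probe_frequency probe frequency, Hz.
#' @param amplitude drive amplitude, mm.
#' @param interval search interval for beta.
#' @param n_grid number of coarse grid points.
#' @param settle transient discarded before measuring the residual, seconds.
#' @param n_periods probe periods in the analysis window.
#' @param seed RNG seed shared by all evaluations.
#' @param tol absolute tolerance on beta for the refinement.
#' @return List with `beta` (the minimizer), `residual` (residual amplitude
#'   at the optimum, mm) and `grid` (`data.frame` of the coarse search).
#' @export
optimize_beta <- function(scene = scene_params(), cal = gain_calibration(),
                          loop = loop_config(), probe_frequency = 0.5,
                          amplitude = 1, interval = c(0.25, 1.75),
                          n_grid = 5, settle = 0.2, n_periods = 1,
                          seed = 1, tol = 0.02) {
  .check_positive(probe_frequency, "probe_frequency")
  dur <- settle + n_periods / probe_frequency + 2 / loop$camera_rate
  traj <- generate_trajectory("sinusoid", amplitude = amplitude,
                              frequency = probe_frequency, duration = dur,
                              rate = 2 * loop$camera_rate)
  objective <- function(beta) {
    cal$beta <- beta
    sim <- simulate_closed_loop(traj, scene, cal, loop, seed = seed)
    trace_amplitude(sim$corrected, probe_frequency, skip = settle)
  }
  bgrid <- seq(interval[1], interval[2], length.out = n_grid)
  vals <- vapply(bgrid, objective, numeric(1))
  i <- which.min(vals)
  if (i > 1L && i < n_grid) {
    dif <- diff(vals)
    if (any(dif[seq_len(i - 1L)] > 0) || any(dif[i:(n_grid - 1L)] < 0)) {
      warning("residual is not unimodal over the beta grid; refining the global grid minimum")
    }
  }
  lo <- bgrid[max(1L, i - 1L)]
  hi <- bgrid[min(n_grid, i + 1L)]
  opt <- optimize(objective, c(lo, hi), tol = tol)
  if (opt$objective <= vals[i]) {
    beta <- opt$minimum; res <- opt$objective
  } else {
    beta <- bgrid[i]; res <- vals[i]
  }
  list(beta = beta, residual = res,
       grid = data.frame(beta = bgrid, residual = vals))
}
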