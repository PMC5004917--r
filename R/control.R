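#' Gain calibration constants
#'
#' The proportional correction gain is assembled from three bench
#' calibrations and one adjustable factor:
#' `g = (mm/pixel) x (deg/mm) x (volts/deg) x beta`,
#' i.e. camera pixel pitch, telecentric scanner angle per millimeter of
#' lateral displacement, scanning-mirror volts per degree, and a unitless
#' loop-gain factor `beta` tuned to minimize residual motion.
#'
#' @param mm_per_pixel camera calibration, mm per camera pixel.
#' @param deg_per_mm scanner calibration, scan-angle degrees per mm of
#'   lateral displacement at the sample. The default corresponds to a
#'   telecentric relay with a 75 mm working distance.
#' @param volts_per_deg scanning-mirror drive calibration, volts per degree.
#' @param beta adjustable gain factor (>= 0).
#' @return An object of class `gain_calibration`.
#' @export
gain_calibration <- function(mm_per_pixel = 0.042, deg_per_mm = 0.764,
                             volts_per_deg = 0.5, beta = 1) {
  .check_positive(mm_per_pixel, "mm_per_pixel")
  .check_positive(deg_per_mm, "deg_per_mm")
  .check_positive(volts_per_deg, "volts_per_deg")
  .check_nonneg(beta, "beta")
  structure(list(mm_per_pixel = mm_per_pixel, deg_per_mm = deg_per_mm,
                 volts_per_deg = volts_per_deg, beta = beta),
            class = "gain_calibration")
}

#' Compute the proportional correction gain
#'
#' @param cal a [gain_calibration()].
#' @return Gain `g` in volts per camera pixel of centroid deviation.
#' @examples
#' compute_gain(gain_calibration(0.042, 1, 0.5, beta = 1)) # 0.021 V/px
#' @export
compute_gain <- function(cal) {
  stopifnot(inherits(cal, "gain_calibration"))
  cal$mm_per_pixel * cal$deg_per_mm * cal$volts_per_deg * cal$beta
}

#' Closed-loop configuration
#'
#' @param camera_rate tracking camera frame rate, Hz.
#' @param latency total loop latency Delta-t in seconds: the delay from
#'   subject motion to the applied scan correction (camera exposure, readout,
#'   processing and output are lumped together).
#' @param tracking_range half-width of the lateral correction clamp, mm; the
#'   applied correction saturates at `+/- tracking_range`.
#' @param reference `(x, y)` designated pupil reference position in camera
#'   pixels, or `NULL` for the frame center.
#' @param hold_max number of consecutive lost-pupil frames over which the
#'   last deviation is held before the correction is reset to zero.
#' @return An object of class `loop_config`.
#' @export
loop_config <- function(camera_rate = 500, latency = 0.004,
                        tracking_range = 2.5, reference = NULL,
                        hold_max = 25L) {
  .check_positive(camera_rate, "camera_rate")
  .check_nonneg(latency, "latency")
  .check_positive(tracking_range, "tracking_range")
  structure(list(camera_rate = camera_rate, latency = latency,
                 tracking_range = tracking_range, reference = reference,
                 hold_max = as.integer(hold_max)),
            class = "loop_config")
}

#' Correction signal for a measured deviation
#'
#' Converts a centroid deviation in camera pixels into the scanner correction:
#' the drive voltage is `-g * deviation` (the correction waveform opposes the
#' measured motion) and the equivalent lateral offset in object space is
#' clamped to the tracking range. Clamping saturates; it never wraps, and the
#' reported voltage is consistent with the clamped offset.
#'
#' @param deviation `(dx, dy)` centroid deviation in pixels.
#' @param cal a [gain_calibration()].
#' @param clamp tracking-range half-width in mm.
#' @return List with `volts` (`c(vx, vy)`) and `mm` (`c(x, y)` applied scan
#'   offset in object space; positive deviation shifts the scan in the
#'   positive direction to follow the pupil).
#' @export
correction_signal <- function(deviation, cal, clamp = 2.5) {
  stopifnot(inherits(cal, "gain_calibration"), length(deviation) == 2L)
  mm_raw <- deviation * cal$mm_per_pixel * cal$beta
  mm <- .clamp(mm_raw, -clamp, clamp)
  volts <- -mm * cal$deg_per_mm * cal$volts_per_deg
  list(volts = volts, mm = mm)
}

# Evaluate the transport-delayed correction waveform at (0-based) tick k:
# linear interpolation of the update sequence u at index k - latency_ticks,
# never newer than the previous tick's update (causality). u entries before
# the first update are zero.
.delayed_value <- function(u, k, lat_ticks) {
  pos <- k - lat_ticks
  pos <- min(pos, k - 1)
  if (pos < 0) return(0)
  i0 <- floor(pos)
  w <- pos - i0
  v0 <- u[i0 + 1L]
  v1 <- if (w > 0) u[min(i0 + 2L, length(u))] else v0
  (1 - w) * v0 + w * v1
}

#' Simulate the pupil-tracking correction loop
#'
#' Discrete-time simulation of the full correction loop replacing the bench
#' hardware. At each camera tick the scene is rendered, the tracker measures
#' the pupil centroid deviation from the reference, and a proportional
#' correction target `u = beta * mm_per_pixel * deviation` is scheduled;
#' corrections take effect after the transport latency Delta-t (the value
#' applied at each tick is the update sequence delayed by `latency`, held
#' between ticks) and are clamped to the tracking range on both axes. The
#' segmentation threshold is determined once from the first frame, as in a
#' live session.
#'
#' By default the camera images the eye directly (`camera_in_loop = FALSE`),
#' matching a tracker whose correction feeds only the OCT scan mirrors, not
#' the camera path: the measured deviation is the absolute pupil
#' displacement, and with an accurate camera calibration and `beta = 1` the
#' applied correction is the subject motion delayed by `latency`, so the
#' residual of a sinusoid of frequency f has amplitude `2 A sin(pi f dt)` --
#' the analytic latency model implemented in [residual_amplitude()]. With
#' `camera_in_loop = TRUE` the frame is instead rendered at the true position
#' minus the applied correction (a camera that looks through the corrected
#' path) and the update becomes incremental,
#' `u = c_applied + beta * mm_per_pixel * deviation`.
#'
#' @param trajectory true pupil motion, a [motion_trace()] sampled at or
#'   above the camera rate.
#' @param scene a [scene_params()].
#' @param cal a [gain_calibration()].
#' @param loop a [loop_config()].
#' @param seed integer RNG seed for the per-frame sensor noise.
#' @param threshold optional fixed gray-level threshold; default selects one
#'   from the first rendered frame.
#' @param camera_in_loop logical; see Details.
#' @return An object of class `simulation_result`: list with `uncorrected`
#'   (apparent motion with tracking off, i.e. the input trajectory at camera
#'   ticks), `corrected` (residual apparent motion with tracking on),
#'   `correction` (applied correction offsets, mm), `residual_std` (standard
#'   deviation of the corrected lateral displacement, mm), `threshold`,
#'   `n_lost` (frames in hold state) and the configuration used.
#' @export
simulate_closed_loop <- function(trajectory, scene = scene_params(),
                                 cal = gain_calibration(),
                                 loop = loop_config(), seed = 1,
                                 threshold = NULL, camera_in_loop = FALSE) {
  stopifnot(inherits(trajectory, "motion_trace"), inherits(scene, "scene_params"),
            inherits(cal, "gain_calibration"), inherits(loop, "loop_config"))
  traj_rate <- trace_rate(trajectory)
  if (!is.na(traj_rate) && traj_rate < loop$camera_rate - 1e-6) {
    .pt_abort("trajectory must be sampled at or above the camera rate",
              "pupiltrack_invalid_parameter")
  }
  rate <- loop$camera_rate
  n <- floor(max(trajectory$t) * rate - 1e-9) + 1L
  tk <- (0:(n - 1)) / rate
  xk <- approx(trajectory$t, trajectory$x, xout = tk, rule = 2)$y
  yk <- approx(trajectory$t, trajectory$y, xout = tk, rule = 2)$y

  set.seed(seed)
  ref <- loop$reference
  if (is.null(ref)) ref <- c((scene$frame_width - 1) / 2, (scene$frame_height - 1) / 2)
  if (is.null(threshold)) {
    f0 <- image_frame(.render_pixels(scene, c(xk[1], yk[1])) + 0,
                      scene$pixel_size)
    threshold <- select_threshold(f0)
  }
  kern <- EBImage::makeBrush(7L, shape = "box")
  lat_ticks <- loop$latency * rate
  rng <- loop$tracking_range
  gain_mm <- cal$mm_per_pixel * cal$beta

  ux <- numeric(n); uy <- numeric(n)      # scheduled correction targets
  cx <- numeric(n); cy <- numeric(n)      # applied corrections
  last_dev <- c(0, 0)
  hold_count <- 0L
  n_lost <- 0L
  H <- scene$frame_height

  for (k in seq_len(n)) {
    cxk <- .delayed_value(ux, k - 1, lat_ticks)
    cyk <- .delayed_value(uy, k - 1, lat_ticks)
    cx[k] <- cxk; cy[k] <- cyk
    if (camera_in_loop) {
      px <- .render_pixels(scene, c(xk[k] - cxk, yk[k] - cyk))
    } else {
      px <- .render_pixels(scene, c(xk[k], yk[k]))
    }
    mask <- (px <= threshold) * 1
    closed <- EBImage::closing(mask, kern)
    lab <- .label8(closed > 0.5)
    counts <- tabulate(lab)
    if (length(counts) > 0L && max(counts) > 0L) {
      big <- which.max(counts)
      idx <- which(lab == big) - 1L
      dev <- c(mean(idx %/% H) - ref[1], mean(idx %% H) - ref[2])
      hold_count <- 0L
    } else {
      n_lost <- n_lost + 1L
      if (hold_count < loop$hold_max) {
        hold_count <- hold_count + 1L
        dev <- last_dev
      } else {
        dev <- NULL # give up: reset the correction to neutral
      }
    }
    if (!is.null(dev)) {
      last_dev <- dev
      base_x <- if (camera_in_loop) cxk else 0
      base_y <- if (camera_in_loop) cyk else 0
      ux[k] <- .clamp(base_x + gain_mm * dev[1], -rng, rng)
      uy[k] <- .clamp(base_y + gain_mm * dev[2], -rng, rng)
    } else {
      ux[k] <- 0; uy[k] <- 0
    }
  }

  corrected_x <- xk - cx
  corrected_y <- yk - cy
  res_std <- sqrt(var(corrected_x) + var(corrected_y))
  structure(list(
    uncorrected = motion_trace(tk, xk, yk),
    corrected = motion_trace(tk, corrected_x, corrected_y),
    correction = motion_trace(tk, cx, cy),
    residual_std = res_std,
    threshold = threshold,
    n_lost = n_lost,
    scene = scene, cal = cal, loop = loop, seed = seed),
    class = "simulation_result")
}

#' @export
print.simulation_result <- function(x, ...) {
  cat(sprintf(
    "<simulation_result> %d ticks at %g Hz, latency %.3g ms, beta %.3g\n  residual std %.4g mm, %d lost frames\n",
    nrow(x$corrected), x$loop$camera_rate, 1000 * x$loop$latency,
    x$cal$beta, x$residual_std, x$n_lost))
  invisible(x)
}

#' Amplitude of a trace at a known drive frequency
#'
#' Estimates the amplitude of the sinusoidal component at `frequency` from
#' the discrete Fourier component over an integer number of periods (robust
#' to broadband noise), or as half the peak-to-peak excursion.
#'
#' @param trace a [motion_trace()]; the x column is analyzed.
#' @param frequency drive frequency, Hz.
#' @param skip initial transient to discard, seconds.
#' @param method `"dft"` or `"peak"`.
#' @return Amplitude in the trace's units.
#' @export
trace_amplitude <- function(trace, frequency, skip = 0,
                            method = c("dft", "peak")) {
  method <- match.arg(method)
  .check_positive(frequency, "frequency")
  t <- trace$t; x <- trace$x
  sel <- t >= skip - 1e-12
  t <- t[sel]; x <- x[sel]
  if (length(x) < 4L) .pt_abort("trace too short", "pupiltrack_invalid_parameter")
  dt <- mean(diff(t))
  np <- floor((t[length(t)] - t[1] + dt) * frequency)
  if (np >= 1) {
    keep <- t < t[1] + np / frequency - 1e-12
    t <- t[keep]; x <- x[keep]
  }
  x <- x - mean(x)
  if (method == "peak") return((max(x) - min(x)) / 2)
  2 * Mod(mean(x * exp(-2i * pi * frequency * t)))
}
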