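#' OCT M-scan acquisition parameters
#'
#' Describes a 2D M-scan: repeated B-scans acquired at a single lateral scan
#' line. Defaults follow a characterization acquisition of 1000 B-scans of
#' 240 A-lines over an 8 mm scan at 416.7 Hz (2.4 s total).
#'
#' @param alines_per_bscan A-lines per B-scan.
#' @param bscan_rate B-scan acquisition rate, Hz.
#' @param n_bscans number of repeated B-scans.
#' @param lateral_fov lateral scan length, mm.
#' @param depth_samples axial samples per A-line.
#' @param speckle_contrast contrast (sd/mean) of the multiplicative speckle
#'   noise; 0 disables it.
#' @param edge_position lateral position of the imaged pupil edge on the scan
#'   line at zero displacement, mm.
#' @param axial_pitch axial sample spacing, mm/sample.
#' @return An object of class `mscan_params`. The implied acquisition
#'   duration is `n_bscans / bscan_rate` and the lateral sampling pitch is
#'   `lateral_fov / alines_per_bscan`.
#' @export
mscan_params <- function(alines_per_bscan = 240L, bscan_rate = 416.7,
                         n_bscans = 1000L, lateral_fov = 8,
                         depth_samples = 128L, speckle_contrast = 0.2,
                         edge_position = 4, axial_pitch = 0.01) {
  .check_positive(alines_per_bscan, "alines_per_bscan")
  .check_positive(bscan_rate, "bscan_rate")
  .check_positive(n_bscans, "n_bscans")
  .check_positive(lateral_fov, "lateral_fov")
  .check_positive(depth_samples, "depth_samples")
  .check_nonneg(speckle_contrast, "speckle_contrast")
  .check_positive(axial_pitch, "axial_pitch")
  structure(list(alines_per_bscan = as.integer(alines_per_bscan),
                 bscan_rate = bscan_rate, n_bscans = as.integer(n_bscans),
                 lateral_fov = lateral_fov,
                 depth_samples = as.integer(depth_samples),
                 speckle_contrast = speckle_contrast,
                 edge_position = edge_position, axial_pitch = axial_pitch),
            class = "mscan_params")
}

#' Construct an M-scan volume
#'
#' @param bscans numeric array `depth x lateral x n_bscans`.
#' @param bscan_rate B-scan rate, Hz.
#' @param lateral_pitch lateral sample spacing, mm/sample.
#' @param axial_pitch axial sample spacing, mm/sample.
#' @return An object of class `mscan_volume`.
#' @export
mscan_volume <- function(bscans, bscan_rate, lateral_pitch, axial_pitch = 0.01) {
  if (!is.array(bscans) || length(dim(bscans)) != 3L) {
    .pt_abort("'bscans' must be a depth x lateral x frames array",
              "pupiltrack_invalid_parameter")
  }
  .check_positive(bscan_rate, "bscan_rate")
  .check_positive(lateral_pitch, "lateral_pitch")
  .check_positive(axial_pitch, "axial_pitch")
  structure(list(bscans = bscans, bscan_rate = bscan_rate,
                 lateral_pitch = lateral_pitch, axial_pitch = axial_pitch),
            class = "mscan_volume")
}

#' @export
print.mscan_volume <- function(x, ...) {
  d <- dim(x$bscans)
  cat(sprintf("<mscan_volume> %d B-scans of %d (depth) x %d (lateral) at %.4g Hz, pitch %.4g mm\n",
              d[3], d[1], d[2], x$bscan_rate, x$lateral_pitch))
  invisible(x)
}

#' Generate a synthetic OCT M-scan volume
#'
#' Each B-scan images a bright-to-dark lateral edge (the pupil boundary seen
#' by the OCT beam) whose instantaneous position is
#' `edge_position - x(t_k)`, the trajectory's lateral displacement sampled at
#' that B-scan's acquisition time. A-lines carry a smooth axial reflectivity
#' profile (a bright surface band over a weak background) and multiplicative
#' unit-mean log-normal speckle with the configured contrast. Deterministic
#' for a fixed seed.
#'
#' @param params an [mscan_params()] object.
#' @param trajectory a [motion_trace()] covering the full acquisition
#'   (`n_bscans / bscan_rate` seconds).
#' @param seed integer RNG seed, or `NULL` for the current stream.
#' @param bright_intensity,dark_intensity mean signal on the bright (iris)
#'   and dark (pupil) side of the edge.
#' @return An [mscan_volume()] with attributes `times` (B-scan timestamps)
#'   and `edge_truth` (ground-truth edge position per B-scan, mm).
#' @export
generate_mscan <- function(params, trajectory, seed = NULL,
                           bright_intensity = 200, dark_intensity = 20) {
  stopifnot(inherits(params, "mscan_params"), inherits(trajectory, "motion_trace"))
  nb <- params$n_bscans
  tb <- (0:(nb - 1)) / params$bscan_rate
  if (max(trajectory$t) < tb[nb] - 1e-9) {
    .pt_abort("trajectory is shorter than the M-scan acquisition",
              "pupiltrack_invalid_parameter")
  }
  if (!is.null(seed)) set.seed(seed)
  A <- params$alines_per_bscan
  D <- params$depth_samples
  pitch <- params$lateral_fov / A
  xk <- approx(trajectory$t, trajectory$x, xout = tb, rule = 2)$y
  edge <- params$edge_position - xk
  # lateral sample centers, mm
  s <- ((0:(A - 1)) + 0.5) * pitch
  # axial profile: weak background plus a bright surface band
  d <- 0:(D - 1)
  prof <- 0.1 + exp(-0.5 * ((d - 0.4 * D) / (0.08 * D))^2)
  prof <- prof / max(prof)
  cc <- params$speckle_contrast
  sdlog <- sqrt(log(1 + cc^2))
  vol <- array(0, dim = c(D, A, nb))
  for (k in seq_len(nb)) {
    cov <- .clamp((edge[k] - s) / pitch + 0.5, 0, 1) # 1 on bright side
    level <- dark_intensity + (bright_intensity - dark_intensity) * cov
    b <- outer(prof, level)
    if (cc > 0) {
      b <- b * exp(rnorm(D * A, -sdlog^2 / 2, sdlog))
    }
    vol[, , k] <- b
  }
  v <- mscan_volume(vol, bscan_rate = params$bscan_rate,
                    lateral_pitch = pitch, axial_pitch = params$axial_pitch)
  attr(v, "times") <- tb
  attr(v, "edge_truth") <- edge
  v
}
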