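#' Summed-voxel projection of an M-scan
#'
#' Collapses each B-scan along depth: the output raster has one row per
#' B-scan (time) and one column per lateral sample, each entry the axial sum
#' of that A-line. Lateral motion of the imaged pupil edge appears as a
#' wandering dark band down the rows.
#'
#' @param volume an [mscan_volume()].
#' @return An [image_frame()] of shape `n_bscans x alines`, pixel pitch set
#'   to the lateral pitch, with attribute `bscan_rate`.
#' @examples
#' tr <- generate_trajectory("constant", duration = 0.1, rate = 1000)
#' v <- generate_mscan(mscan_params(n_bscans = 40, speckle_contrast = 0), tr)
#' dim(svp(v)$pixels) # 40 B-scans x 240 lateral samples
#' @export
svp <- function(volume) {
  stopifnot(inherits(volume, "mscan_volume"))
  d <- dim(volume$bscans)
  out <- t(apply(volume$bscans, 3L, colSums))
  if (d[3] == 1L) out <- matrix(out, nrow = 1L)
  f <- image_frame(out, pixel_size = volume$lateral_pitch)
  attr(f, "bscan_rate") <- volume$bscan_rate
  f
}

#' Fast-axis motion trace from sequential B-scan cross-correlation
#'
#' Estimates the lateral shift between each pair of consecutive B-scans as
#' the argmax of the normalized 1D cross-correlation of their depth-summed
#' lateral profiles, then integrates (cumulative sum) to produce the
#' fast-axis motion trace, timestamped at the B-scan rate. Positive values
#' mean image content moved toward higher lateral sample indices. No
#' detrending is applied to the integrated trace.
#'
#' Shifts are integer-sample by default (argmax of the normalized
#' cross-correlation over the full profiles). With `refine = TRUE` each pair
#' is instead correlated over a lightly smoothed window centered on the
#' strongest intensity edge, and the correlation is maximized over a
#' continuous lag (linear profile interpolation), giving sub-sample
#' resolution; the windowing keeps the featureless plateaus of the profile
#' from diluting the edge information under speckle.
#'
#' @param volume an [mscan_volume()] with at least 2 B-scans.
#' @param max_lag largest per-pair shift searched, in lateral samples.
#' @param refine logical; sub-sample refinement of each shift (see Details).
#' @param units `"mm"` (via the lateral pitch) or `"samples"`.
#' @return A [motion_trace()]. Flat, featureless B-scans raise an error of
#'   class `pupiltrack_undefined_shift`.
#' @export
bscan_xcorr_trace <- function(volume, max_lag = NULL, refine = FALSE,
                              units = c("mm", "samples")) {
  stopifnot(inherits(volume, "mscan_volume"))
  units <- match.arg(units)
  d <- dim(volume$bscans)
  if (d[3] < 2L) {
    .pt_abort("need at least 2 B-scans", "pupiltrack_invalid_parameter")
  }
  prof <- apply(volume$bscans, 3L, colSums) # lateral x frames
  if (is.null(max_lag)) max_lag <- max(2L, min(30L, d[2] %/% 4L))
  est <- if (refine) {
    function(a, b) .xcorr_shift_subsample(a, b, max_lag = max_lag)
  } else {
    function(a, b) .xcorr_shift(a, b, max_lag = max_lag)
  }
  shifts <- vapply(2:d[3], function(k) {
    est(prof[, k - 1L], prof[, k])
  }, numeric(1))
  cum <- cumsum(c(0, shifts))
  t <- (0:(d[3] - 1L)) / volume$bscan_rate
  x <- if (units == "mm") cum * volume$lateral_pitch else cum
  motion_trace(t, x, 0, units = units)
}

# Sub-sample pairwise shift: smooth both profiles with a 3-sample moving
# average, window around the strongest gradient of the reference, and
# maximize the normalized correlation over a continuous lag via linear
# interpolation of the moving profile. Window half-width of 8 samples keeps
# noise from the flat plateaus out of the estimate.
.xcorr_shift_subsample <- function(a, b, max_lag, half_width = 8L) {
  if (sd(a) == 0 || sd(b) == 0) {
    .pt_abort("featureless input: shift undefined", "pupiltrack_undefined_shift")
  }
  k <- rep(1 / 3, 3)
  a2 <- as.numeric(stats::filter(a, k, sides = 2)); a2[is.na(a2)] <- a[is.na(a2)]
  b2 <- as.numeric(stats::filter(b, k, sides = 2)); b2[is.na(b2)] <- b[is.na(b2)]
  e <- which.max(abs(diff(a2)))
  lo <- max(1L, e - half_width); hi <- min(length(a2), e + half_width)
  aw <- a2[lo:hi] - mean(a2[lo:hi])
  idx <- lo:hi
  nb <- seq_along(b2)
  obj <- function(s) {
    bs <- approx(nb, b2, xout = idx + s, rule = 2)$y
    bb <- bs - mean(bs)
    den <- sqrt(sum(aw^2) * sum(bb^2))
    if (den == 0) 0 else -sum(aw * bb) / den
  }
  coarse <- -min(3L, max_lag):min(3L, max_lag)
  cc <- vapply(coarse, obj, numeric(1))
  i0 <- coarse[which.min(cc)]
  if (abs(i0) == max(coarse) && max(coarse) < max_lag) {
    # large shift: fall back to the integer estimate to center the search
    i0 <- .xcorr_shift(a, b, max_lag = max_lag)
  }
  optimize(obj, c(i0 - 1, i0 + 1))$minimum
}

# Integer 2D shift with zero fill.
.shift2d <- function(m, dr, dc) {
  H <- nrow(m); W <- ncol(m)
  out <- matrix(0, H, W)
  src_r <- seq_len(H) - dr
  src_c <- seq_len(W) - dc
  ok_r <- src_r >= 1L & src_r <= H
  ok_c <- src_c >= 1L & src_c <= W
  out[which(ok_r), which(ok_c)] <- m[src_r[ok_r], src_c[ok_c]]
  out
}

#' Register repeated B-scans and average
#'
#' Aligns every B-scan to the first by cross-correlation and averages the
#' aligned stack. `axial_only` registration estimates depth shifts from the
#' laterally-summed depth profiles (what B-scan averaging can always do);
#' `full` registration additionally estimates lateral shifts from the
#' depth-summed lateral profiles. Shifts are applied as integer sample
#' offsets with zero fill.
#'
#' @param volume an [mscan_volume()] with at least 2 B-scans.
#' @param mode `"axial_only"` or `"full"`.
#' @param max_lag largest shift searched, samples.
#' @return An [image_frame()] holding the averaged B-scan (depth x lateral);
#'   attribute `shifts` is a `data.frame` of the per-frame offsets.
#' @export
register_average <- function(volume, mode = c("axial_only", "full"),
                             max_lag = 20L) {
  stopifnot(inherits(volume, "mscan_volume"))
  mode <- match.arg(mode)
  d <- dim(volume$bscans)
  if (d[3] < 2L) {
    .pt_abort("need at least 2 B-scans", "pupiltrack_invalid_parameter")
  }
  ref_ax <- rowSums(volume$bscans[, , 1L])
  ref_lat <- colSums(volume$bscans[, , 1L])
  acc <- matrix(0, d[1], d[2])
  shifts <- data.frame(frame = seq_len(d[3]), axial = 0, lateral = 0)
  for (k in seq_len(d[3])) {
    b <- volume$bscans[, , k]
    da <- if (k == 1L) 0 else round(.xcorr_shift(ref_ax, rowSums(b), max_lag))
    dl <- 0
    if (mode == "full" && k > 1L) {
      dl <- round(.xcorr_shift(ref_lat, colSums(b), max_lag))
    }
    shifts$axial[k] <- da
    shifts$lateral[k] <- dl
    acc <- acc + .shift2d(b, -da, -dl)
  }
  out <- image_frame(acc / d[3], pixel_size = volume$lateral_pitch)
  attr(out, "shifts") <- shifts
  out
}

#' Standard deviation of a motion trace
#'
#' Sample standard deviation of the displacement values of one axis --
#' the summary used to compare tracked and untracked acquisitions.
#'
#' @param trace a [motion_trace()] with at least 2 samples.
#' @param axis `"x"` or `"y"`.
#' @return Standard deviation in the trace's units.
#' @export
trace_std <- function(trace, axis = c("x", "y")) {
  axis <- match.arg(axis)
  if (nrow(trace) < 2L) {
    .pt_abort("need at least 2 samples", "pupiltrack_invalid_parameter")
  }
  sd(trace[[axis]])
}
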