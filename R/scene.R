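#' Pupil-camera scene parameters
#'
#' Describes the synthetic dark-pupil/bright-iris scene imaged by the tracking
#' camera. The defaults mirror a 500 Hz oculography camera running at a
#' downsampled 320 x 256 pixel resolution with a 42 um pixel pitch (13.4 x
#' 10.8 mm field of view). IR illumination reflected by the iris and
#' transmitted by the pupil yields a bimodal intensity histogram: a dark disk
#' (the pupil) on a bright background (the iris/sclera).
#'
#' @param frame_width,frame_height frame size in pixels.
#' @param pixel_size physical pixel pitch, mm/pixel.
#' @param pupil_radius pupil radius in mm. Default 2 mm (a 4 mm diameter
#'   pupil, typical indoors).
#' @param iris_intensity,pupil_intensity mean gray levels (8-bit scale) of the
#'   bright background and the dark pupil disk.
#' @param noise_sigma standard deviation of additive Gaussian sensor noise in
#'   gray levels.
#' @param artifacts list of small dark blob artifacts (eyelash shadows and the
#'   like); each element is a list with `center` (x, y in mm relative to the
#'   frame center), `radius` (pixels) and `intensity` (gray level).
#' @return An object of class `scene_params`.
#' @export
scene_params <- function(frame_width = 320L, frame_height = 256L,
                         pixel_size = 0.042, pupil_radius = 2,
                         iris_intensity = 200, pupil_intensity = 20,
                         noise_sigma = 10, artifacts = list()) {
  .check_positive(frame_width, "frame_width")
  .check_positive(frame_height, "frame_height")
  .check_positive(pixel_size, "pixel_size")
  .check_positive(pupil_radius, "pupil_radius")
  .check_nonneg(noise_sigma, "noise_sigma")
  if (pupil_intensity >= iris_intensity) {
    .pt_abort("'pupil_intensity' must be below 'iris_intensity' (dark pupil on bright iris)",
              "pupiltrack_invalid_parameter")
  }
  r_px <- pupil_radius / pixel_size
  if (2 * r_px > min(frame_width, frame_height)) {
    .pt_abort("pupil does not fit in the frame at zero offset",
              "pupiltrack_invalid_parameter")
  }
  structure(list(frame_width = as.integer(frame_width),
                 frame_height = as.integer(frame_height),
                 pixel_size = pixel_size, pupil_radius = pupil_radius,
                 iris_intensity = iris_intensity,
                 pupil_intensity = pupil_intensity,
                 noise_sigma = noise_sigma, artifacts = artifacts),
            class = "scene_params")
}

# Paint an anti-aliased dark disk onto `px` (matrix, rows = y). Center in
# 0-based pixel coordinates. Coverage of boundary pixels is approximated
# linearly from the signed distance to the circle, which is accurate enough
# for sub-pixel centroid work.
.paint_disk <- function(px, cx, cy, r, level) {
  H <- nrow(px); W <- ncol(px)
  c0 <- max(0L, floor(cx - r - 1)); c1 <- min(W - 1L, ceiling(cx + r + 1))
  r0 <- max(0L, floor(cy - r - 1)); r1 <- min(H - 1L, ceiling(cy + r + 1))
  if (c0 > c1 || r0 > r1) return(px)
  xs <- c0:c1; ys <- r0:r1
  d <- sqrt(outer((ys - cy)^2, (xs - cx)^2, "+"))
  cov <- .clamp(r - d + 0.5, 0, 1)
  sub <- px[ys + 1L, xs + 1L, drop = FALSE]
  px[ys + 1L, xs + 1L] <- sub - (sub - level) * cov
  px
}

# Render the scene at the given pupil center (mm relative to frame center)
# using the *current* RNG stream. Returns a plain integer-valued matrix.
.render_pixels <- function(scene, center) {
  W <- scene$frame_width; H <- scene$frame_height; ps <- scene$pixel_size
  px <- matrix(scene$iris_intensity, H, W)
  cx <- (W - 1) / 2 + center[1] / ps
  cy <- (H - 1) / 2 + center[2] / ps
  r <- scene$pupil_radius / ps
  degenerate <- (cx + r < -0.5) || (cx - r > W - 0.5) ||
    (cy + r < -0.5) || (cy - r > H - 0.5)
  if (!degenerate) px <- .paint_disk(px, cx, cy, r, scene$pupil_intensity)
  for (a in scene$artifacts) {
    px <- .paint_disk(px,
                      (W - 1) / 2 + a$center[1] / ps,
                      (H - 1) / 2 + a$center[2] / ps,
                      a$radius, a$intensity)
  }
  if (scene$noise_sigma > 0) px <- px + rnorm(length(px), 0, scene$noise_sigma)
  px <- round(.clamp(px, 0, 255))
  attr(px, "degenerate") <- degenerate
  px
}

#' Generate a synthetic pupil-camera frame
#'
#' Renders a dark pupil disk on a bright iris background at the requested
#' center, with anti-aliased disk edges, optional dark-blob artifacts and
#' additive Gaussian noise. Deterministic for a fixed seed.
#'
#' A pupil that falls entirely outside the frame does not raise an error; the
#' returned frame simply contains no disk and carries the attribute
#' `degenerate = TRUE` so downstream code can flag the detection as lost.
#'
#' @param scene a [scene_params()] object.
#' @param center pupil center `(x, y)` in mm relative to the frame center
#'   (x rightward, y downward).
#' @param seed integer RNG seed, or `NULL` to use the current RNG stream.
#' @param timestamp acquisition time in seconds.
#' @return An [image_frame()]; gray levels are integers in `[0, 255]`.
#' @examples
#' f <- generate_pupil_frame(scene_params(noise_sigma = 0), center = c(0.5, -0.3))
#' range(f$pixels)
#' @export
generate_pupil_frame <- function(scene, center = c(0, 0), seed = NULL,
                                 timestamp = 0) {
  stopifnot(inherits(scene, "scene_params"), length(center) == 2L)
  if (!is.null(seed)) set.seed(seed)
  px <- .render_pixels(scene, center)
  f <- image_frame(matrix(as.numeric(px), nrow(px), ncol(px)),
                   pixel_size = scene$pixel_size, timestamp = timestamp)
  attr(f, "degenerate") <- attr(px, "degenerate")
  attr(f, "true_center") <- center
  f
}
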