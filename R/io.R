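#' Write a frame sequence as a multi-page TIFF
#'
#' 8-bit integer gray levels round-trip exactly.
#'
#' @param frames list of [image_frame()] objects with gray levels in
#'   `[0, 255]`.
#' @param path output `.tif` path.
#' @return The path, invisibly.
#' @export
write_frames <- function(frames, path) {
  stopifnot(length(frames) > 0L)
  pages <- lapply(frames, function(f) f$pixels / 255)
  tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  invisible(path)
}

#' Read a frame sequence from a multi-page TIFF
#'
#' @param path input `.tif` path.
#' @param pixel_size physical pixel pitch to attach, mm/pixel.
#' @param rate optional frame rate in Hz used to assign timestamps.
#' @return List of [image_frame()] objects.
#' @export
read_frames <- function(path, pixel_size = 0.042, rate = NULL) {
  if (!file.exists(path)) {
    .pt_abort(sprintf("file not found: %s", path), "pupiltrack_io_error")
  }
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  lapply(seq_along(pages), function(i) {
    px <- pages[[i]]
    if (length(dim(px)) == 3L) px <- px[, , 1L] # drop extra channels
    image_frame(round(px * 255), pixel_size = pixel_size,
                timestamp = if (is.null(rate)) 0 else (i - 1) / rate)
  })
}

#' Write a motion trace as CSV
#'
#' Plain CSV with header `t,x,y` (seconds, mm, mm).
#'
#' @param trace a [motion_trace()].
#' @param path output `.csv` path.
#' @return The path, invisibly.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "motion_trace"))
  write.csv(trace[, c("t", "x", "y")], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a motion trace from CSV
#'
#' @param path input `.csv` with columns `t`, `x`, `y`.
#' @return A [motion_trace()].
#' @export
read_trace <- function(path) {
  if (!file.exists(path)) {
    .pt_abort(sprintf("file not found: %s", path), "pupiltrack_io_error")
  }
  df <- read.csv(path)
  for (col in c("t", "x", "y")) {
    if (!col %in% names(df)) {
      .pt_abort(sprintf("malformed trace file %s: missing column '%s'", path, col),
                "pupiltrack_parse_error")
    }
  }
  motion_trace(df$t, df$x, df$y)
}

#' Write an M-scan volume (multi-page TIFF plus JSON sidecar)
#'
#' One TIFF page per B-scan (32-bit float, scaled to `[0, 1]`), with the
#' acquisition metadata and the intensity scale in a JSON sidecar
#' (`<path>.json`) so the volume can be reconstructed.
#'
#' @param volume an [mscan_volume()].
#' @param path output `.tif` path.
#' @return The path, invisibly.
#' @export
write_mscan <- function(volume, path) {
  stopifnot(inherits(volume, "mscan_volume"))
  d <- dim(volume$bscans)
  scale <- max(volume$bscans)
  if (scale <= 0) scale <- 1
  pages <- lapply(seq_len(d[3]), function(k) volume$bscans[, , k] / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  meta <- list(n_bscans = d[3], depth_samples = d[1], alines_per_bscan = d[2],
               bscan_rate = volume$bscan_rate,
               lateral_pitch = volume$lateral_pitch,
               axial_pitch = volume$axial_pitch, intensity_scale = scale)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an M-scan volume written by [write_mscan()]
#'
#' @param path `.tif` path with a `<path>.json` sidecar.
#' @return An [mscan_volume()].
#' @export
read_mscan <- function(path) {
  sidecar <- paste0(path, ".json")
  if (!file.exists(path) || !file.exists(sidecar)) {
    .pt_abort(sprintf("M-scan file or sidecar missing for %s", path),
              "pupiltrack_io_error")
  }
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  vol <- array(0, dim = c(meta$depth_samples, meta$alines_per_bscan, length(pages)))
  for (k in seq_along(pages)) vol[, , k] <- pages[[k]] * meta$intensity_scale
  mscan_volume(vol, bscan_rate = meta$bscan_rate,
               lateral_pitch = meta$lateral_pitch,
               axial_pitch = meta$axial_pitch)
}

#' Assemble an experiment configuration
#'
#' @param scene a [scene_params()] or a list of its arguments.
#' @param calibration a [gain_calibration()] or argument list.
#' @param loop a [loop_config()] or argument list.
#' @param mscan an [mscan_params()] or argument list.
#' @param seeds non-empty integer vector of RNG seeds.
#' @param output_dir directory for experiment artifacts.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(scene = scene_params(),
                              calibration = gain_calibration(),
                              loop = loop_config(), mscan = mscan_params(),
                              seeds = 1L, output_dir = ".") {
  build <- function(x, ctor, cls, section) {
    if (inherits(x, cls)) return(x)
    if (!is.list(x)) {
      .pt_abort(sprintf("config section '%s' must be a list", section),
                "pupiltrack_invalid_config")
    }
    known <- names(formals(ctor))
    bad <- setdiff(names(x), known)
    if (length(bad) > 0L) {
      .pt_abort(sprintf("config section '%s': unknown field '%s'", section, bad[1L]),
                "pupiltrack_invalid_config")
    }
    tryCatch(do.call(ctor, x), error = function(e) {
      .pt_abort(sprintf("config section '%s': %s", section, conditionMessage(e)),
                "pupiltrack_invalid_config")
    })
  }
  scene <- build(scene, scene_params, "scene_params", "scene")
  calibration <- build(calibration, gain_calibration, "gain_calibration", "calibration")
  loop <- build(loop, loop_config, "loop_config", "loop")
  mscan <- build(mscan, mscan_params, "mscan_params", "mscan")
  if (length(seeds) == 0L || any(!is.finite(seeds))) {
    .pt_abort("config field 'seeds' must be a non-empty vector of integers",
              "pupiltrack_invalid_config")
  }
  structure(list(scene = scene, calibration = calibration, loop = loop,
                 mscan = mscan, seeds = as.integer(seeds),
                 output_dir = output_dir),
            class = "experiment_config")
}

#' Read an experiment configuration from a YAML file
#'
#' Expects top-level sections `scene`, `calibration`, `loop`, `mscan` (each a
#' mapping of the corresponding constructor's arguments; missing sections use
#' package defaults), plus `seeds` and `output_dir`.
#'
#' @param path YAML file path.
#' @return An [experiment_config()].
#' @export
read_config <- function(path) {
  if (!file.exists(path)) {
    .pt_abort(sprintf("config file not found: %s", path), "pupiltrack_io_error")
  }
  y <- yaml::read_yaml(path)
  known <- c("scene", "calibration", "loop", "mscan", "seeds", "output_dir")
  bad <- setdiff(names(y), known)
  if (length(bad) > 0L) {
    .pt_abort(sprintf("unknown config section '%s'", bad[1L]),
              "pupiltrack_invalid_config")
  }
  experiment_config(
    scene = if (is.null(y$scene)) scene_params() else y$scene,
    calibration = if (is.null(y$calibration)) gain_calibration() else y$calibration,
    loop = if (is.null(y$loop)) loop_config() else y$loop,
    mscan = if (is.null(y$mscan)) mscan_params() else y$mscan,
    seeds = if (is.null(y$seeds)) 1L else unlist(y$seeds),
    output_dir = if (is.null(y$output_dir)) "." else y$output_dir)
}
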