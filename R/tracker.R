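#' Select a segmentation threshold from a bimodal frame
#'
#' The dark-pupil/bright-iris scene yields a bimodal gray-level histogram, so
#' a single intensity threshold separates pupil from background. Mirroring a
#' tracker that fixes its threshold once at the start of a session, the
#' default method lightly smooths the 256-bin histogram, locates its two
#' dominant modes, and returns the gray level of the valley between them.
#' Otsu's criterion is available as an alternative.
#'
#' @param frame an [image_frame()] with integer gray levels in `[0, 255]`.
#' @param method `"valley"` (histogram valley between the two largest modes)
#'   or `"otsu"`.
#' @param smooth_sigma Gaussian sigma (in gray levels) for histogram
#'   smoothing before peak/valley search.
#' @param min_separation minimum distance in gray levels between the two
#'   modes; closer secondary peaks are treated as part of the main mode.
#' @return Threshold gray level (numeric scalar). Errors with condition class
#'   `pupiltrack_no_valley` when the histogram has no second mode (e.g. a
#'   uniform frame), in which case a threshold must be supplied manually.
#' @export
select_threshold <- function(frame, method = c("valley", "otsu"),
                             smooth_sigma = 2, min_separation = 16) {
  stopifnot(inherits(frame, "image_frame"))
  method <- match.arg(method)
  px <- frame$pixels
  if (method == "otsu") {
    return(EBImage::otsu(px / 255, range = c(0, 1), levels = 256) * 255)
  }
  h <- tabulate(as.integer(px) + 1L, nbins = 256L)
  k <- max(3L, ceiling(3 * smooth_sigma))
  kern <- stats::dnorm(-k:k, sd = smooth_sigma)
  kern <- kern / sum(kern)
  hp <- c(rep(h[1], k), h, rep(h[256], k))
  hs <- as.numeric(stats::filter(hp, kern, sides = 2))[(k + 1L):(k + 256L)]
  # local maxima (plateau-tolerant at the right edge); an endpoint counts
  # only when strictly above its neighbor, and empty bins never do
  left <- c(hs[2], hs[-256])
  right <- c(hs[-1], hs[255])
  peaks <- which(hs > left & hs >= right & hs > 0)
  if (length(peaks) < 2L) {
    .pt_abort("histogram has no valley (unimodal frame); supply a threshold manually",
              "pupiltrack_no_valley")
  }
  peaks <- peaks[order(hs[peaks], decreasing = TRUE)]
  p1 <- peaks[1L]
  p2 <- peaks[which(abs(peaks - p1) >= min_separation)[1L]]
  if (is.na(p2)) {
    .pt_abort("histogram has no valley (single dominant mode); supply a threshold manually",
              "pupiltrack_no_valley")
  }
  lo <- min(p1, p2); hi <- max(p1, p2)
  v <- which.min(hs[(lo + 1L):(hi - 1L)]) + lo
  v - 1  # bin index 1 corresponds to gray level 0
}

#' Binarize a frame and apply morphological closing
#'
#' Pixels at or below the threshold are marked foreground (the pupil is
#' dark), then morphological closing with a 7 x 7 square structuring element
#' is applied to the foreground to clean up the pupil blob (filling small
#' concavities and holes caused by e.g. eyelash shadows or specular noise)
#' before the centroid is computed.
#'
#' @param frame an [image_frame()].
#' @param threshold gray level; pixels `<= threshold` become foreground.
#' @param kernel_size side of the square closing kernel in pixels.
#' @return Integer 0/1 matrix of the closed foreground mask.
#' @export
binarize_and_close <- function(frame, threshold, kernel_size = 7L) {
  stopifnot(inherits(frame, "image_frame"))
  if (threshold < 0 || threshold > 255) {
    .pt_abort("'threshold' outside the gray-level range [0, 255]",
              "pupiltrack_invalid_parameter")
  }
  mask <- (frame$pixels <= threshold) * 1
  kern <- EBImage::makeBrush(as.integer(kernel_size), shape = "box")
  closed <- EBImage::closing(mask, kern)
  out <- matrix(as.integer(closed > 0.5), nrow(mask), ncol(mask))
  out
}

# Exact 8-connectivity labelling: EBImage::bwlabel is 4-connected, so merge
# labels that touch diagonally with a small union-find over the label graph.
.label8 <- function(mask) {
  lab <- EBImage::imageData(EBImage::bwlabel(mask))
  nl <- max(lab)
  if (nl <= 1L) return(lab)
  H <- nrow(lab); W <- ncol(lab)
  dr <- cbind(as.vector(lab[-H, -W]), as.vector(lab[-1, -1]))   # down-right
  dl <- cbind(as.vector(lab[-H, -1]), as.vector(lab[-1, -W]))   # down-left
  pr <- rbind(dr, dl)
  pr <- pr[pr[, 1] > 0 & pr[, 2] > 0 & pr[, 1] != pr[, 2], , drop = FALSE]
  if (nrow(pr) == 0L) return(lab)
  pr <- unique(pr)
  parent <- seq_len(nl)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (r in seq_len(nrow(pr))) {
    a <- find(pr[r, 1]); b <- find(pr[r, 2])
    if (a != b) parent[max(a, b)] <- min(a, b)
  }
  root <- vapply(seq_len(nl), find, integer(1))
  map <- c(0L, as.integer(root))
  matrix(map[lab + 1L], H, W)
}

#' Locate the largest connected component and its centroid
#'
#' Labels the foreground with 8-connectivity, selects the largest-area blob
#' (assumed to be the pupil), and reports the unweighted center of mass of
#' its pixels with sub-pixel precision in 0-based `(x, y)` pixel coordinates.
#' Ties in area are broken toward the blob whose centroid lies nearest the
#' reference position, where the pupil is expected.
#'
#' @param binary 0/1 matrix (e.g. from [binarize_and_close()]).
#' @param reference optional `(x, y)` reference position for tie-breaking.
#' @return An object of class `pupil_detection`: list with `centroid`
#'   (`c(x, y)`, pixels), `area` (pixels), `threshold_used` and `valid`.
#'   Empty foreground yields `valid = FALSE` rather than an error.
#' @export
largest_component_centroid <- function(binary, reference = NULL) {
  lab <- .label8(binary > 0)
  counts <- tabulate(lab)
  if (length(counts) == 0L || max(counts) == 0L) {
    return(structure(list(centroid = c(NA_real_, NA_real_), area = 0L,
                          threshold_used = NA_real_, valid = FALSE),
                     class = "pupil_detection"))
  }
  amax <- max(counts)
  cand <- which(counts == amax)
  H <- nrow(lab)
  cent_of <- function(l) {
    idx <- which(lab == l) - 1L
    c(mean(idx %/% H), mean(idx %% H)) # (x = col, y = row), 0-based
  }
  if (length(cand) > 1L && !is.null(reference)) {
    cents <- vapply(cand, cent_of, numeric(2))
    d2 <- (cents[1, ] - reference[1])^2 + (cents[2, ] - reference[2])^2
    best <- cand[which.min(d2)]
  } else {
    best <- cand[1L]
  }
  structure(list(centroid = cent_of(best), area = amax,
                 threshold_used = NA_real_, valid = TRUE),
            class = "pupil_detection")
}

#' @export
print.pupil_detection <- function(x, ...) {
  if (x$valid) {
    cat(sprintf("<pupil_detection> centroid (%.2f, %.2f) px, area %d px\n",
                x$centroid[1], x$centroid[2], x$area))
  } else {
    cat("<pupil_detection> invalid (no foreground)\n")
  }
  invisible(x)
}

#' Track the pupil in one frame
#'
#' Full single-frame pipeline: binarize at the session threshold, close with
#' the 7 x 7 kernel, take the largest 8-connected blob, and report the
#' deviation of its centroid from the designated reference position in camera
#' pixels. A lost pupil (no foreground) is reported with `valid = FALSE` so
#' the control loop can hold its last correction instead of failing.
#'
#' @param frame an [image_frame()].
#' @param threshold session gray-level threshold (see [select_threshold()]).
#' @param reference `(x, y)` reference position in pixels; defaults to the
#'   frame center.
#' @return List with `deviation` (`c(dx, dy)` in pixels, `NA` when invalid),
#'   `valid`, and the underlying `detection`.
#' @export
track_frame <- function(frame, threshold, reference = NULL) {
  stopifnot(inherits(frame, "image_frame"))
  if (is.null(reference)) {
    reference <- c((ncol(frame$pixels) - 1) / 2, (nrow(frame$pixels) - 1) / 2)
  }
  bin <- binarize_and_close(frame, threshold)
  det <- largest_component_centroid(bin, reference = reference)
  det$threshold_used <- threshold
  if (det$valid) {
    list(deviation = det$centroid - reference, valid = TRUE, detection = det)
  } else {
    list(deviation = c(NA_real_, NA_real_), valid = FALSE, detection = det)
  }
}

#' Track a sequence of frames
#'
#' Applies [track_frame()] to a list of frames with a single session
#' threshold, returning one row per frame in the layout used by the CSV
#' detection export.
#'
#' @param frames list of [image_frame()] objects.
#' @param threshold session threshold; if `NULL`, selected from the first
#'   frame via [select_threshold()].
#' @param reference reference position, defaulting to the frame center.
#' @return `data.frame` with columns `frame`, `t`, `cx`, `cy`, `area`,
#'   `valid`.
#' @export
track_frames <- function(frames, threshold = NULL, reference = NULL) {
  stopifnot(length(frames) > 0L)
  if (is.null(threshold)) threshold <- select_threshold(frames[[1L]])
  rows <- lapply(seq_along(frames), function(i) {
    r <- track_frame(frames[[i]], threshold, reference)
    data.frame(frame = i, t = frames[[i]]$timestamp,
               cx = r$detection$centroid[1], cy = r$detection$centroid[2],
               area = r$detection$area, valid = r$valid)
  })
  do.call(rbind, rows)
}
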