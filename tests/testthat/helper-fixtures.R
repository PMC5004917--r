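# Shared fixtures and independent oracles used across the test files.

# Small camera scene: same pixel pitch and intensity structure as the default
# scene, but a quarter of the pixels, to keep loop simulations fast.
small_scene <- function(noise_sigma = 10, ...) {
  scene_params(frame_width = 128L, frame_height = 104L, pupil_radius = 0.8,
               noise_sigma = noise_sigma, ...)
}

# Brute-force 8-connected component labelling by breadth-first flood fill.
# Independent of the package's bwlabel + union-find path.
bf_label8 <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(0L, H, W)
  cur <- 0L
  for (j in seq_len(W)) for (i in seq_len(H)) {
    if (mask[i, j] && lab[i, j] == 0L) {
      cur <- cur + 1L
      queue <- list(c(i, j))
      lab[i, j] <- cur
      while (length(queue) > 0L) {
        p <- queue[[1L]]; queue <- queue[-1L]
        for (di in -1:1) for (dj in -1:1) {
          ii <- p[1] + di; jj <- p[2] + dj
          if (ii >= 1L && ii <= H && jj >= 1L && jj <= W &&
              mask[ii, jj] && lab[ii, jj] == 0L) {
            lab[ii, jj] <- cur
            queue[[length(queue) + 1L]] <- c(ii, jj)
          }
        }
      }
    }
  }
  lab
}

# Centroid/area of the largest blob from a brute-force labelling,
# 0-based (x, y) convention.
bf_largest_centroid <- function(mask) {
  lab <- bf_label8(mask)
  if (max(lab) == 0L) return(NULL)
  counts <- tabulate(lab)
  big <- which.max(counts)
  idx <- which(lab == big, arr.ind = TRUE)
  list(centroid = c(mean(idx[, 2]) - 1, mean(idx[, 1]) - 1),
       area = counts[big])
}

# Hand-rolled binary morphology on small grids (dilation then erosion with a
# square kernel), used as the oracle for closing.
bf_dilate <- function(mask, k) {
  r <- (k - 1L) %/% 2L
  H <- nrow(mask); W <- ncol(mask)
  out <- matrix(0L, H, W)
  for (i in seq_len(H)) for (j in seq_len(W)) {
    ii <- max(1L, i - r):min(H, i + r)
    jj <- max(1L, j - r):min(W, j + r)
    out[i, j] <- as.integer(any(mask[ii, jj] > 0))
  }
  out
}

bf_erode <- function(mask, k) {
  r <- (k - 1L) %/% 2L
  H <- nrow(mask); W <- ncol(mask)
  out <- matrix(0L, H, W)
  for (i in seq_len(H)) for (j in seq_len(W)) {
    ii <- max(1L, i - r):min(H, i + r)
    jj <- max(1L, j - r):min(W, j + r)
    out[i, j] <- as.integer(all(mask[ii, jj] > 0))
  }
  out
}

bf_close <- function(mask, k = 7L) bf_erode(bf_dilate(mask, k), k)

# Residual amplitude ratio of the simulated loop at one drive frequency.
sim_residual_ratio <- function(f, scene, cal, loop, seed = 1, settle = 0.2,
                               amplitude = 1) {
  dur <- settle + max(2 / f, 0.4) + 2 / loop$camera_rate
  tr <- generate_trajectory("sinusoid", amplitude = amplitude, frequency = f,
                            duration = dur, rate = 2 * loop$camera_rate)
  sim <- simulate_closed_loop(tr, scene, cal, loop, seed = seed)
  trace_amplitude(sim$corrected, f, skip = settle) /
    trace_amplitude(sim$uncorrected, f, skip = settle)
}
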