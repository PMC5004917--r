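test_that("threshold selection lands in the valley of a bimodal histogram", {
  f <- generate_pupil_frame(scene_params(noise_sigma = 0), seed = 1)
  th <- select_threshold(f)
  expect_gt(th, 20); expect_lt(th, 200)
  # binary mask equals the painted disk away from the anti-aliased rim
  mask <- f$pixels <= th
  core <- f$pixels <= 20
  expect_true(all(mask[core]))
  expect_lt(sum(mask) - sum(core), 400) # only rim pixels differ

  # uniform frame: no valley
  flat <- image_frame(matrix(128, 64, 64), 0.042)
  expect_error(select_threshold(flat), class = "pupiltrack_no_valley")

  # noisy frame: agree with a brute-force valley search on the smoothed histogram
  fn <- generate_pupil_frame(scene_params(noise_sigma = 10), seed = 2)
  thn <- select_threshold(fn)
  h <- tabulate(as.integer(fn$pixels) + 1L, 256L)
  ks <- stats::dnorm(-6:6, sd = 2); ks <- ks / sum(ks)
  hs <- as.numeric(stats::filter(c(rep(h[1], 6), h, rep(h[256], 6)), ks))[7:262]
  valley <- which.min(hs[30:190]) + 29 - 1
  expect_lt(abs(thn - valley), 15)

  # Otsu alternative also separates the modes
  tho <- select_threshold(fn, method = "otsu")
  expect_gt(tho, 20); expect_lt(tho, 200)
})

test_that("closing matches a hand-executed dilation-then-erosion oracle", {
  set.seed(42)
  for (rep in 1:5) {
    m <- matrix(0L, 20L, 20L)
    # a blob with a bite taken out, plus scattered noise
    m[6:15, 6:15] <- 1L
    m[9:11, 14:15] <- 0L
    noise <- matrix(runif(400) < 0.05, 20L, 20L)
    m[noise] <- 1L
    fr <- image_frame(matrix(ifelse(m == 1L, 10, 200), 20L, 20L), 0.042)
    got <- binarize_and_close(fr, 100)
    expect_identical(got, bf_close(m, 7L))
  }
})

test_that("closing is idempotent and preserves a clean convex disk", {
  f <- generate_pupil_frame(scene_params(noise_sigma = 0), seed = 1)
  b1 <- binarize_and_close(f, 110)
  fr2 <- image_frame(matrix(ifelse(b1 == 1L, 0, 255), nrow(b1), ncol(b1)), 0.042)
  b2 <- binarize_and_close(fr2, 128)
  expect_identical(b1, b2)
  expect_true(all(b1 %in% c(0L, 1L)))
  # plain disk: closing leaves the thresholded disk unchanged
  raw <- (f$pixels <= 110) * 1L
  expect_lt(sum(abs(b1 - raw)), 10)
})

test_that("largest-component centroid agrees with a brute-force oracle on random rasters", {
  set.seed(99)
  for (rep in 1:25) {
    H <- sample(5:32, 1); W <- sample(5:32, 1)
    mask <- matrix(runif(H * W) < 0.35, H, W)
    det <- largest_component_centroid(mask * 1L)
    oracle <- bf_largest_centroid(mask)
    if (is.null(oracle)) {
      expect_false(det$valid)
    } else {
      expect_true(det$valid)
      expect_equal(det$area, oracle$area)
      # areas can tie; centroid must then match one of the tied blobs
      if (det$area == oracle$area && !isTRUE(all.equal(det$centroid, oracle$centroid))) {
        lab <- bf_label8(mask)
        counts <- tabulate(lab)
        tied <- which(counts == max(counts))
        cents <- lapply(tied, function(l) {
          idx <- which(lab == l, arr.ind = TRUE)
          c(mean(idx[, 2]) - 1, mean(idx[, 1]) - 1)
        })
        expect_true(any(vapply(cents, function(cc) isTRUE(all.equal(cc, det$centroid)), logical(1))))
      } else {
        expect_equal(det$centroid, oracle$centroid, tolerance = 1e-9)
      }
    }
  }
})

test_that("blob selection picks the largest area and ties break toward the reference", {
  m <- matrix(0L, 40L, 60L)
  m[5:24, 5:29] <- 1L   # 500 px
  m[30:39, 40:59] <- 1L # 200 px
  det <- largest_component_centroid(m)
  expect_equal(det$area, 500L)
  expect_equal(det$centroid, c(16, 13.5), tolerance = 1e-9) # 0-based (x, y)

  # equal areas: nearest to the reference wins
  m2 <- matrix(0L, 30L, 30L)
  m2[2:6, 2:6] <- 1L
  m2[22:26, 22:26] <- 1L
  near_tl <- largest_component_centroid(m2, reference = c(0, 0))
  near_br <- largest_component_centroid(m2, reference = c(29, 29))
  expect_equal(near_tl$centroid, c(3, 3))
  expect_equal(near_br$centroid, c(23, 23))

  expect_false(largest_component_centroid(matrix(0L, 10L, 10L))$valid)
})

test_that("track_frame reports deviations in pixels and handles a lost pupil", {
  sc <- scene_params(noise_sigma = 0)
  f <- generate_pupil_frame(sc, center = c(0.42, 0), seed = 1)
  th <- select_threshold(f)
  r <- track_frame(f, th)
  expect_equal(r$deviation[1], 10, tolerance = 0.2)
  expect_equal(r$deviation[2], 0, tolerance = 0.2)

  centered <- generate_pupil_frame(sc, center = c(0, 0), seed = 2)
  r0 <- track_frame(centered, th)
  expect_lt(max(abs(r0$deviation)), 0.2)

  # 1 mm step is ~23.8 px at 42 um pixels
  stepped <- generate_pupil_frame(sc, center = c(1, 0), seed = 3)
  rs <- track_frame(stepped, th)
  expect_equal(rs$deviation[1], 1 / 0.042, tolerance = 0.5)

  blank <- image_frame(matrix(200, 64L, 64L), 0.042)
  rb <- track_frame(blank, 100)
  expect_false(rb$valid)
  expect_true(all(is.na(rb$deviation)))
})

test_that("end-to-end centroid accuracy holds across the frame, with and without noise", {
  sc0 <- scene_params(noise_sigma = 0)
  th <- select_threshold(generate_pupil_frame(sc0, seed = 1))
  centers <- rbind(c(0, 0), c(2, 1), c(-3, -2), c(-4.5, 0), c(0, 3.2), c(3.5, -2.5))
  for (i in seq_len(nrow(centers))) {
    f <- generate_pupil_frame(sc0, center = centers[i, ], seed = 10 + i)
    r <- track_frame(f, th)
    expect_lt(max(abs(r$deviation - centers[i, ] / sc0$pixel_size)), 0.5)
  }
  # noisy: RMS error under 1 px over repeated draws
  scn <- scene_params(noise_sigma = 10)
  thn <- select_threshold(generate_pupil_frame(scn, seed = 30))
  errs <- vapply(1:20, function(i) {
    cen <- c(runif(1, -2, 2), runif(1, -1.5, 1.5))
    f <- generate_pupil_frame(scn, center = cen, seed = 100 + i)
    r <- track_frame(f, thn)
    sqrt(sum((r$deviation - cen / scn$pixel_size)^2))
  }, numeric(1))
  expect_lt(sqrt(mean(errs^2)), 1)
})

test_that("small artifacts move the centroid by less than a pixel", {
  sc <- scene_params(noise_sigma = 0)
  th <- select_threshold(generate_pupil_frame(sc, seed = 1))
  clean <- track_frame(generate_pupil_frame(sc, center = c(1, 0.5), seed = 2), th)
  # artifact area ~113 px << 25% of the ~7120 px pupil
  sca <- scene_params(noise_sigma = 0, artifacts = list(
    list(center = c(-3, -2), radius = 6, intensity = 10)))
  dirty <- track_frame(generate_pupil_frame(sca, center = c(1, 0.5), seed = 2), th)
  expect_lt(max(abs(dirty$deviation - clean$deviation)), 1)
})
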