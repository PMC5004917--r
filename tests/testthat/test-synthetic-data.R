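test_that("pupil frames have the configured geometry and a bimodal histogram", {
  f <- generate_pupil_frame(scene_params(noise_sigma = 0), center = c(0, 0), seed = 1)
  expect_equal(dim(f$pixels), c(256L, 320L))
  expect_equal(f$pixel_size, 0.042)
  # noiseless frame: exactly two gray-level populations (plus edge pixels)
  h <- tabulate(as.integer(f$pixels) + 1L, 256L)
  expect_gt(h[21], 0)   # pupil level 20
  expect_gt(h[201], 0)  # iris level 200
  expect_gt(h[21] + h[201], 0.95 * length(f$pixels))
  # bimodality with a valley persists for noise below half the intensity gap
  for (sg in c(5, 10, 30)) {
    fn <- generate_pupil_frame(scene_params(noise_sigma = sg), seed = 2)
    expect_silent(th <- select_threshold(fn))
    expect_gt(th, 20); expect_lt(th, 200)
  }
})

test_that("frame generation is reproducible and flags an off-frame pupil", {
  sc <- scene_params()
  f1 <- generate_pupil_frame(sc, center = c(0.3, 0.2), seed = 7)
  f2 <- generate_pupil_frame(sc, center = c(0.3, 0.2), seed = 7)
  expect_identical(f1$pixels, f2$pixels)
  f3 <- generate_pupil_frame(sc, center = c(50, 0), seed = 7)
  expect_true(attr(f3, "degenerate"))
  expect_false(attr(f1, "degenerate"))
  # no dark disk in a degenerate frame
  expect_gt(min(f3$pixels), 100)
})

test_that("generator round trip: tracker recovers the painted center", {
  sc <- scene_params(noise_sigma = 0)
  f <- generate_pupil_frame(sc, center = c(0.5, -0.3), seed = 3)
  th <- select_threshold(f)
  r <- track_frame(f, th)
  expect_true(r$valid)
  expect_lt(max(abs(r$deviation - c(0.5, -0.3) / sc$pixel_size)), 0.5)
})

test_that("deterministic trajectories match their definitions", {
  tr <- generate_trajectory("sinusoid", amplitude = 1, frequency = 1,
                            duration = 2, rate = 1000)
  expect_equal(tr$x[tr$t == 0.25], 1, tolerance = 1e-9)
  expect_equal(max(tr$x), 1, tolerance = 1e-6)

  st <- generate_trajectory("step", amplitude = 3, duration = 1, rate = 1000)
  expect_equal(st$x[st$t == 0.25], 0)
  expect_equal(st$x[st$t == 0.75], 3)

  ct <- generate_trajectory("constant", duration = 1, rate = 500)
  expect_equal(nrow(ct), 500L)
  expect_true(all(ct$x == 0))

  expect_error(generate_trajectory("sinusoid", frequency = 300, duration = 1, rate = 500),
               class = "pupiltrack_invalid_parameter")
  expect_error(generate_trajectory("step", duration = -1, rate = 500),
               class = "pupiltrack_invalid_parameter")
})

test_that("fixational trajectories are seeded, 1/f-sloped, and low-frequency dominated", {
  a <- generate_fixational_trajectory(seed = 11)
  b <- generate_fixational_trajectory(seed = 11)
  expect_identical(a, b)
  expect_equal(sqrt(mean(a$x^2 + a$y^2)), 0.1, tolerance = 1e-9)

  # periodogram slope over [0.5, 50] Hz for a pure 1/f drift component
  tr <- generate_fixational_trajectory(duration = 10, rate = 500,
                                       psd_exponent = 1,
                                       microsaccade_rate = 0, seed = 5)
  x <- tr$x - mean(tr$x); n <- length(x)
  p <- Mod(fft(x))[2:(n %/% 2)]^2
  f <- (1:(n %/% 2 - 1)) * 500 / n
  sel <- f >= 0.5 & f <= 50
  slope <- unname(coef(lm(log(p[sel]) ~ log(f[sel])))[2])
  expect_lt(abs(slope - (-1)), 0.3)

  # defaults: majority of spectral power below 10 Hz
  d <- generate_fixational_trajectory(seed = 6)
  z <- (d$x - mean(d$x)) + 1i * (d$y - mean(d$y)); n <- length(z)
  p <- Mod(fft(z))^2
  fr <- (0:(n - 1)) * 500 / n; fr[fr > 250] <- 500 - fr[fr > 250]
  frac <- sum(p[fr > 0 & fr <= 10]) / sum(p[fr > 0])
  expect_gt(frac, 0.5)

  expect_error(generate_fixational_trajectory(rate = 50, seed = 1),
               class = "pupiltrack_invalid_parameter")
  expect_error(generate_fixational_trajectory(psd_exponent = 3, seed = 1),
               class = "pupiltrack_invalid_parameter")
})

test_that("M-scan volumes encode the trajectory in the edge position", {
  mp <- mscan_params(n_bscans = 1000L, bscan_rate = 416.7)
  # acquisition duration 2.4 s, lateral pitch 33.3 um
  expect_equal(mp$n_bscans / mp$bscan_rate, 2.4, tolerance = 1e-3)
  expect_equal(mp$lateral_fov / mp$alines_per_bscan, 1 / 30, tolerance = 1e-9)

  tr <- generate_trajectory("sinusoid", 0.5, 2, duration = 2.4, rate = 1000)
  v <- generate_mscan(mscan_params(speckle_contrast = 0), tr, seed = 1)
  expect_equal(dim(v$bscans), c(128L, 240L, 1000L))
  # noiseless ground truth: per-B-scan edge column within one lateral sample
  sv <- svp(v)
  edge_cols <- apply(sv$pixels, 1L, function(r) which.max(abs(diff(r))))
  truth <- attr(v, "edge_truth") / v$lateral_pitch
  expect_lt(max(abs(edge_cols - truth)), 1.0)

  # constant trajectory: straight edge
  ct <- generate_trajectory("constant", duration = 0.3, rate = 1000)
  v2 <- generate_mscan(mscan_params(n_bscans = 100L, speckle_contrast = 0), ct, seed = 2)
  cols <- apply(svp(v2)$pixels, 1L, function(r) which.max(abs(diff(r))))
  expect_equal(length(unique(cols)), 1L)

  # determinism and the too-short-trajectory error
  v3 <- generate_mscan(mscan_params(n_bscans = 50L), ct, seed = 9)
  v4 <- generate_mscan(mscan_params(n_bscans = 50L), ct, seed = 9)
  expect_identical(v3$bscans, v4$bscans)
  expect_error(generate_mscan(mscan_params(), generate_trajectory("constant", duration = 1, rate = 1000)),
               class = "pupiltrack_invalid_parameter")
})
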