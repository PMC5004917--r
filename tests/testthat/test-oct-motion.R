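test_that("SVP sums along depth with the right shape", {
  vol <- mscan_volume(array(1, c(16, 24, 5)), bscan_rate = 100,
                      lateral_pitch = 0.033)
  sv <- svp(vol)
  expect_equal(dim(sv$pixels), c(5L, 24L))
  expect_true(all(sv$pixels == 16))

  # generated M-scan: dark band follows the trajectory within one sample
  tr <- generate_trajectory("sinusoid", 0.3, 2, duration = 1.2, rate = 1000)
  v <- generate_mscan(mscan_params(n_bscans = 500L, speckle_contrast = 0), tr, seed = 1)
  sv2 <- svp(v)
  expect_equal(dim(sv2$pixels), c(500L, 240L))
  cols <- apply(sv2$pixels, 1L, function(r) which.max(abs(diff(r))))
  expect_lt(max(abs(cols - attr(v, "edge_truth") / v$lateral_pitch)), 1)
})

test_that("sequential cross-correlation recovers constructed shifts", {
  # identical B-scans: all-zero trace
  b <- matrix(1, 8, 48)
  b[, 12:22] <- 6
  b[, 30:34] <- 3
  vol <- mscan_volume(array(rep(b, 6), c(8, 48, 6)), 100, 0.033)
  expect_true(all(bscan_xcorr_trace(vol, units = "samples")$x == 0))

  # frame k = frame 0 shifted by k samples
  tr <- generate_trajectory("constant", duration = 0.2, rate = 1000)
  v0 <- generate_mscan(mscan_params(n_bscans = 5L, speckle_contrast = 0), tr, seed = 1)
  b0 <- v0$bscans[, , 1]
  arr <- array(0, c(dim(b0), 5))
  arr[, , 1] <- b0
  for (k in 2:5) {
    pad <- matrix(b0[, 1], nrow(b0), k - 1)
    arr[, , k] <- cbind(pad, b0[, 1:(ncol(b0) - k + 1)])
  }
  v <- mscan_volume(arr, 100, v0$lateral_pitch)
  got <- bscan_xcorr_trace(v, units = "samples")
  expect_equal(got$x, 0:4)
  expect_equal(bscan_xcorr_trace(v)$x, (0:4) * v0$lateral_pitch, tolerance = 1e-9)

  # featureless volume: undefined shift
  flat <- mscan_volume(array(3, c(8, 32, 4)), 100, 0.033)
  expect_error(bscan_xcorr_trace(flat), class = "pupiltrack_undefined_shift")
})

test_that("round trip: xcorr trace recovers the trajectory within one sample RMS", {
  traj <- generate_trajectory("sinusoid", 0.5, 2, duration = 2.4, rate = 1000)
  for (contrast in c(0.2, 0.3)) {
    v <- generate_mscan(mscan_params(speckle_contrast = contrast), traj, seed = 7)
    xc <- bscan_xcorr_trace(v, refine = TRUE, units = "samples")
    xk <- approx(traj$t, traj$x, attr(v, "times"))$y
    # image content moves opposite to the displacement
    truth <- -(xk - xk[1]) / v$lateral_pitch
    expect_lt(sqrt(mean((xc$x - truth)^2)), 1)
    # correlation with the driving motion is strong
    expect_gt(abs(cor(xc$x, xk)), 0.9)
  }
})

test_that("edge trace and xcorr trace agree on the same volume", {
  traj <- generate_trajectory("sinusoid", 0.5, 2, duration = 2.4, rate = 1000)
  v <- generate_mscan(mscan_params(), traj, seed = 7)
  et <- extract_edge_trace(svp(v), units = "samples")
  xc <- bscan_xcorr_trace(v, refine = TRUE, units = "samples")
  d <- (et$x - et$x[1]) - xc$x
  expect_lt(sqrt(mean(d^2)), 2)
})

test_that("registration removes constructed offsets and full beats axial-only", {
  tr <- generate_trajectory("constant", duration = 0.2, rate = 1000)
  v0 <- generate_mscan(mscan_params(n_bscans = 8L, speckle_contrast = 0.1), tr, seed = 2)

  shift2 <- function(m, dr, dc) {
    o <- matrix(0, nrow(m), ncol(m))
    sr <- seq_len(nrow(m)) - dr; sc <- seq_len(ncol(m)) - dc
    okr <- sr >= 1 & sr <= nrow(m); okc <- sc >= 1 & sc <= ncol(m)
    o[which(okr), which(okc)] <- m[sr[okr], sc[okc]]
    o
  }
  set.seed(3)
  ax <- c(0, sample(-5:5, 7, replace = TRUE))
  lt <- c(0, sample(-4:4, 7, replace = TRUE))
  arr <- v0$bscans
  for (k in 1:8) arr[, , k] <- shift2(v0$bscans[, , k], ax[k], lt[k])
  v <- mscan_volume(arr, v0$bscan_rate, v0$lateral_pitch)

  # identical B-scans: average equals any single B-scan
  vid <- mscan_volume(array(rep(v0$bscans[, , 1], 4), c(dim(v0$bscans)[1:2], 4)),
                      100, v0$lateral_pitch)
  avg_id <- register_average(vid, "full")
  expect_equal(avg_id$pixels, v0$bscans[, , 1], tolerance = 1e-9)

  # axial-only mode recovers the injected axial offsets exactly
  ra <- register_average(v, "axial_only")
  expect_equal(attr(ra, "shifts")$axial, ax)
  expect_true(all(attr(ra, "shifts")$lateral == 0))

  # full registration also recovers lateral offsets and sharpens the average
  rf <- register_average(v, "full")
  expect_equal(attr(rf, "shifts")$lateral, lt)
  grad_energy <- function(img) mean(diff(t(img$pixels))^2)
  expect_gte(grad_energy(rf), grad_energy(ra))
})

test_that("trace_std follows the sample-standard-deviation conventions", {
  expect_equal(trace_std(motion_trace((0:9) / 10, rep(2, 10))), 0)
  alt <- motion_trace((0:99) / 100, rep(c(-1, 1), 50))
  expect_equal(trace_std(alt), sd(rep(c(-1, 1), 50)), tolerance = 1e-12)
  expect_equal(trace_std(alt), 1, tolerance = 0.01)
  t <- (0:9999) / 1000
  sine <- motion_trace(t, 0.4 * sin(2 * pi * 5 * t))
  expect_equal(trace_std(sine), 0.4 / sqrt(2), tolerance = 0.001)
  expect_error(trace_std(motion_trace(0, 1)), class = "pupiltrack_invalid_parameter")
})

test_that("tracking reduces fixational motion std at least twofold end to end", {
  traj <- generate_fixational_trajectory(duration = 2.4, rate = 1000, seed = 9)
  sim <- simulate_closed_loop(traj, scene_params(), gain_calibration(),
                              loop_config(), seed = 10)
  mp <- mscan_params()
  v_off <- generate_mscan(mp, sim$uncorrected, seed = 11)
  v_on <- generate_mscan(mp, sim$corrected, seed = 12)
  std_off <- trace_std(bscan_xcorr_trace(v_off, refine = TRUE))
  std_on <- trace_std(bscan_xcorr_trace(v_on, refine = TRUE))
  expect_gte(std_off / std_on, 2)
})
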