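test_that("outlier detector flags a spiked frame and nothing on clean data", {
  mask <- array(TRUE, c(4, 4, 3))
  # constant series: no flags
  qc0 <- detect_outlier_frames(const_series(nt = 20), mask)
  expect_false(any(qc0$outlier_flags))

  # noisy series with one frame spiked by 20 sd
  set.seed(8)
  nt <- 30
  prof <- 100 + rnorm(nt, 0, 0.5)
  prof[17] <- prof[17] + 20 * 0.5
  s <- profile_series(prof)
  qc <- detect_outlier_frames(s, mask, threshold = 3)
  expect_true(qc$outlier_flags[17])
  expect_equal(which(qc$outlier_flags), 17L)

  # infinite threshold: nothing can exceed it
  qcInf <- detect_outlier_frames(s, mask, threshold = Inf)
  expect_false(any(qcInf$outlier_flags))

  expect_error(detect_outlier_frames(s, array(FALSE, c(4, 4, 3))), "mask")
  expect_error(detect_outlier_frames(const_series(nt = 4), mask), "5 frames")
})

test_that("frame means in QC equal direct masked means", {
  set.seed(11)
  arr <- array(runif(4 * 4 * 3 * 8, 50, 150), c(4, 4, 3, 8))
  s <- volume_series(arr, tr = 30, te = 0.035)
  mask <- array(FALSE, c(4, 4, 3)); mask[1:2, , ] <- TRUE
  qc <- detect_outlier_frames(s, mask)
  direct <- sapply(1:8, function(k) mean(arr[1:2, , , k]))
  expect_equal(qc$frame_mean, direct, tolerance = 1e-12)
})

test_that("spatial smoothing preserves DC, mass, and matches the brute-force oracle", {
  expect_error(spatial_smooth(array(1, c(8, 8, 8)), kernel_width = 4), "odd")

  const <- array(5, c(8, 8, 8))
  expect_equal(spatial_smooth(const)[4, 4, 4], 5, tolerance = 1e-12)

  imp <- array(0, c(9, 9, 9)); imp[5, 5, 5] <- 3
  sm <- spatial_smooth(imp)
  expect_equal(sum(sm), 3, tolerance = 1e-12)  # unit-sum kernel

  set.seed(3)
  vol <- array(runif(8^3), c(8, 8, 8))
  expect_equal(spatial_smooth(vol, 5, 1.5),
               brute_conv3(vol, 5, 1.5), tolerance = 1e-10)

  # linearity: smooth(a * S) = a * smooth(S)
  expect_equal(spatial_smooth(3.7 * vol), 3.7 * spatial_smooth(vol),
               tolerance = 1e-12)
})

test_that("mask-aware smoothing does not bleed signal across the ROI edge", {
  vol <- array(0, c(8, 8, 8))
  mask <- array(FALSE, c(8, 8, 8)); mask[3:6, 3:6, 3:6] <- TRUE
  vol[mask] <- 2
  sm <- spatial_smooth(vol, mask = mask)
  expect_equal(sm[mask], rep(2, sum(mask)), tolerance = 1e-12)
  expect_equal(sm[!mask], vol[!mask])  # untouched outside
})

test_that("temporal smoothing is exact on constants, identities and ramps", {
  s <- const_series(v = 42, nt = 20, tr = 60)
  out <- temporal_smooth(s, window = 10)
  expect_equal(as.vector(out$data), rep(42, length(out$data)))

  # window 1 on a uniform grid: interpolation only, values unchanged
  set.seed(5)
  prof <- runif(20, 50, 60)
  s2 <- profile_series(prof)
  out2 <- temporal_smooth(s2, window = 1)
  expect_equal(out2$data[1, 1, 1, ], prof, tolerance = 1e-12)

  # moving average of a linear ramp is the ramp in the interior
  ramp <- seq(10, 29, by = 1)
  out3 <- temporal_smooth(profile_series(ramp), window = 5)
  inner <- 4:17
  expect_equal(out3$data[2, 2, 2, inner], ramp[inner], tolerance = 1e-10)

  expect_error(temporal_smooth(s, window = 50), "window")
})

test_that("temporal smoothing drops flagged frames before interpolating", {
  prof <- rep(100, 20); prof[8] <- 500
  s <- profile_series(prof)
  qc <- list(outlier_flags = seq_along(prof) == 8)
  out <- temporal_smooth(s, window = 1, qc = qc)
  expect_true(all(abs(out$data - 100) < 1e-9))
})

test_that("baseline map averages unflagged baseline frames only", {
  s <- const_series(v = 90, nt = 30, tr = 60)  # 30 frames over 29 min
  bl <- compute_baseline(s, paradigm10)
  expect_equal(bl, array(90, c(4, 4, 3)))

  prof <- rep(100, 30); prof[4] <- 1000
  s2 <- profile_series(prof)
  # without QC the spike contaminates; with the spike flagged it is
  # excluded and the baseline is the mean of the remaining frames
  bl_raw <- compute_baseline(s2, paradigm10)
  expect_equal(bl_raw[1, 1, 1], mean(prof[1:10]))
  qc <- list(outlier_flags = seq_len(30) == 4)
  bl_qc <- compute_baseline(s2, paradigm10, qc)
  expect_equal(bl_qc[1, 1, 1], 100)

  # all baseline frames flagged -> error
  qc_all <- list(outlier_flags = c(rep(TRUE, 10), rep(FALSE, 20)))
  expect_error(compute_baseline(s2, paradigm10, qc_all), "baseline")
})

test_that("outlier false-positive rate stays low on pure noise", {
  set.seed(123)
  fp <- replicate(20, {
    prof <- 100 + rnorm(40, 0, 1)
    qc <- detect_outlier_frames(profile_series(prof), array(TRUE, c(4, 4, 3)),
                                threshold = 3)
    mean(qc$outlier_flags)
  })
  expect_lt(mean(fp), 0.05)
})
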