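test_that("delta-R2* follows the log-ratio closed form and sign convention", {
  # S / S_baseline = exp(0.35) at TE = 35 ms -> exactly 10 s^-1
  base <- array(100, c(4, 4, 3))
  prof <- c(100, 100 * exp(0.35), 100 * exp(-0.07), 100)
  s <- profile_series(prof, te = 0.035)
  d <- delta_r2star(s, base)
  expect_equal(d$data[2, 2, 2, ], c(0, 10, -2, 0), tolerance = 1e-10)
  expect_true(all(d$valid))
})

test_that("voxels with nonpositive baseline are flagged invalid", {
  base <- array(100, c(4, 4, 3)); base[1, 1, 1] <- 0
  s <- const_series(v = 100, nt = 4)
  d <- delta_r2star(s, base)
  expect_false(d$valid[1, 1, 1])
  expect_true(all(is.na(d$data[1, 1, 1, ])))
  expect_true(d$valid[2, 2, 2])
})

test_that("ROI curves equal the brute-force masked mean and sd", {
  set.seed(21)
  shape <- c(5, 4, 3); nt <- 6
  arr <- array(runif(prod(shape) * nt, 80, 120), c(shape, nt))
  s <- volume_series(arr, tr = 60, te = 0.035)
  d <- delta_r2star(s, array(100, shape))
  lab <- array(0L, shape); lab[2:4, 2:3, 1:2] <- 1L
  rois <- roi_set(lab, c(placenta_twinA = 1L))
  cv <- roi_curve(d, rois, "placenta_twinA")
  for (k in seq_len(nt)) {
    vals <- d$data[, , , k][lab == 1L]
    expect_equal(cv$mean[k], mean(vals), tolerance = 1e-12)
    expect_equal(cv$sd[k], sd(vals), tolerance = 1e-12)
  }
  expect_equal(cv$n_voxels, sum(lab == 1L))

  # single-voxel ROI: curve equals the voxel, sd = 0
  lab1 <- array(0L, shape); lab1[1, 1, 1] <- 1L
  cv1 <- roi_curve(d, roi_set(lab1, c(placenta_twinA = 1L)), "placenta_twinA")
  expect_equal(cv1$mean, d$data[1, 1, 1, ])
  expect_true(all(cv1$sd == 0))

  lab0 <- array(0L, shape)
  expect_error(roi_curve(d, roi_set(lab0, c(placenta_twinA = 1L)),
                         "placenta_twinA"), "valid voxels")
})

test_that("spline slope reproduces lines, constants and the model derivative", {
  t <- seq(0, 30, by = 0.1)
  expect_equal(curve_slope(list(t = t, mean = 2.5 * t - 3), 13), 2.5,
               tolerance = 1e-8)
  expect_equal(curve_slope(list(t = t, mean = rep(4, length(t))), 9), 0,
               tolerance = 1e-10)
  # smooth gamma-model curve: spline derivative matches the numerical
  # derivative of the model at an interior time within 2% (curvature
  # well resolved by the 2-min knot spacing)
  pr <- list(alpha = 2, beta = 3, delta = 0.5, c1 = 0, c2 = 8)
  y <- model_eval(pr, t, paradigm10)
  at <- 16
  h <- 1e-5
  truth <- (model_eval(pr, at + h, paradigm10) -
            model_eval(pr, at - h, paradigm10)) / (2 * h)
  expect_equal(curve_slope(list(t = t, mean = y), at), truth,
               tolerance = 0.02)
  expect_error(curve_slope(list(t = t, mean = y), 31), "support")
})

test_that("amplitude summaries capture plateau, peak and post-epoch mean", {
  t <- seq(0, 29.9, by = 0.1)
  zero <- list(t = t, mean = rep(0, length(t)))
  s0 <- amplitude_summary(zero, paradigm10)
  expect_equal(unlist(s0), c(max_abs = 0, last2min_mean = 0,
                             end_post_value = 0))

  step <- list(t = t, mean = ifelse(t >= 10 & t <= 20, 5, 0))
  st <- amplitude_summary(step, paradigm10)
  expect_equal(st$last2min_mean, 5)
  expect_equal(st$max_abs, 5)

  undershoot <- list(t = t, mean = ifelse(t > 25, -1.2, 0))
  expect_lt(amplitude_summary(undershoot, paradigm10)$end_post_value, 0)

  short <- list(t = seq(0, 5, 0.1), mean = rep(0, 51))
  expect_error(amplitude_summary(short, paradigm10), "hyperoxia")
})

test_that("forward signal model and delta-R2* are exact inverses", {
  tv <- voxel_truth(alpha = 2, beta = 2, delta = 1, c1 = 0.3, c2 = 7)
  t <- seq(0, 29.9, by = 0.1)
  sim <- simulate_voxel_series(tv, paradigm10, te = 0.035,
                               s_baseline = 500, noise_sd = 0, t = t)
  recovered <- log(sim$signal / 500) / 0.035
  expect_equal(recovered, sim$dr2s_model, tolerance = 1e-12)
})
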