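test_that("Friedman statistic matches closed form and printed p-values", {
  # 7 pairs, larger twin always in the same column
  res <- friedman_test(cbind(rep(1, 7), rep(2, 7)))
  expect_equal(res$chi2, 7)
  expect_equal(round(res$p, 3), 0.008)

  # exactly one discordant pair
  m <- cbind(rep(1, 7), rep(2, 7)); m[3, ] <- c(2, 1)
  res1 <- friedman_test(m)
  expect_equal(res1$chi2, 25 / 7, tolerance = 1e-12)
  expect_equal(res1$rank_sums, c(8, 13), ignore_attr = TRUE)
  expect_equal(round(res1$p, 2), 0.06)

  # fully tied blocks: mid-ranks give chi2 = 0, p = 1
  expect_equal(friedman_test(cbind(rep(3, 5), rep(3, 5)))$chi2, 0)
  expect_equal(friedman_test(cbind(rep(3, 5), rep(3, 5)))$p, 1)

  expect_error(friedman_test(cbind(c(1, NA), c(2, 3))), "missing")
  expect_error(friedman_test(matrix(1, 1, 2)), "2 blocks")
})

test_that("Friedman agrees with enumeration and the reference implementation", {
  # brute-force oracle: all 2^7 concordance patterns for k = 2, n = 7
  n <- 7
  for (pattern in 0:(2^n - 1)) {
    flip <- as.logical(bitwAnd(pattern, 2^(0:(n - 1))))
    blocks <- t(vapply(flip, function(f) if (f) c(2, 1) else c(1, 2),
                       numeric(2)))
    # independent closed form: rank sums from the flip count
    w <- sum(flip)
    r1 <- 2 * w + (n - w); r2 <- w + 2 * (n - w)
    chi2_oracle <- 12 / (n * 2 * 3) * (r1^2 + r2^2) - 3 * n * 3
    res <- friedman_test(blocks)
    expect_equal(res$chi2, chi2_oracle, tolerance = 1e-12)
  }
  # cross-check against the reference implementation on tie-free data
  set.seed(10)
  y <- matrix(rnorm(14), 7, 2)
  expect_equal(friedman_test(y)$chi2,
               unname(stats::friedman.test(y)$statistic))
  expect_equal(friedman_test(y)$p, stats::friedman.test(y)$p.value)
})

test_that("pair-resampled Spearman is exact on monotone data and seeded", {
  # y strictly increasing in x for every possible twin selection
  pairs <- data.frame(pair_id = rep(1:7, each = 2),
                      x = c(1, 2, 11, 12, 21, 22, 31, 32, 41, 42, 51, 52,
                            61, 62))
  pairs$y <- pairs$x^2 + 5
  res <- pair_resampled_spearman(pairs, "x", "y", reps = 200, seed = 3)
  expect_equal(res$median_r, 1.0)
  expect_equal(res$n_degenerate, 0)

  r1 <- pair_resampled_spearman(pairs, "x", "y", reps = 1, seed = 8)
  r2 <- pair_resampled_spearman(pairs, "x", "y", reps = 1, seed = 8)
  expect_identical(r1$median_r, r2$median_r)

  # independent x and y: weak median correlation over seeds
  set.seed(4)
  ind <- data.frame(pair_id = rep(1:7, each = 2),
                    x = rnorm(14), y = rnorm(14))
  meds <- sapply(1:5, function(s)
    pair_resampled_spearman(ind, "x", "y", reps = 200, seed = s)$median_r)
  expect_true(all(abs(meds) < 0.5))

  expect_error(pair_resampled_spearman(pairs[1:6, ], "x", "y"), "4 pairs")
})

test_that("resampled Spearman median stabilizes at 1000 reps", {
  set.seed(6)
  dat <- data.frame(pair_id = rep(1:12, each = 2),
                    x = rnorm(24))
  dat$y <- 0.7 * dat$x + rnorm(24, 0, 0.5)
  meds <- sapply(1:4, function(s)
    pair_resampled_spearman(dat, "x", "y", reps = 1000, seed = s)$median_r)
  expect_lt(max(meds) - min(meds), 0.02 + 1e-9)
})

test_that("mixed model matches OLS when pair variance is nil and flags collinearity", {
  set.seed(12)
  n <- 40
  tab <- data.frame(pair_id = rep(1:(n / 2), each = 2),
                    x1 = rnorm(n), x2 = rnorm(n))
  tab$y <- 3 + 2 * tab$x1 - 1 * tab$x2 + rnorm(n, 0, 0.3)  # no pair effect
  mm <- suppressMessages(mixed_model_fit(tab, "y", c("x1", "x2")))
  ols <- coef(lm(y ~ x1 + x2, tab))
  if (mm$ranef_sd < 1e-8) {
    expect_equal(mm$coefficients$estimate, unname(ols), tolerance = 1e-6)
  } else {
    expect_equal(mm$coefficients$estimate, unname(ols), tolerance = 0.05)
  }

  tab$x3 <- tab$x1
  expect_error(mixed_model_fit(tab, "y", c("x1", "x3")), "collinear")
  expect_error(mixed_model_fit(tab, "y", "nope"), "missing columns")
})

test_that("mixed model recovers the generating TTP -> birth-weight slope", {
  co <- generate_cohort(cohort_spec(bw_slope = 100, bw_sga_deficit = 0),
                        paradigm10, seed = 17)
  mm <- mixed_model_fit(co$records, "birth_weight",
                        c("ttp_mean", "ga_at_mri"))
  row <- mm$coefficients[mm$coefficients$term == "ttp_mean", ]
  expect_lt(abs(row$estimate - (-100)), 2 * row$se)
})

test_that("FDA group curves give flat t on identical groups and Welch t on offsets", {
  t <- seq(0, 30, by = 0.25)
  base <- sin(t / 5) + 0.1 * t
  curves <- rbind(matrix(rep(base, 4), 4, byrow = TRUE),
                  matrix(rep(base, 4), 4, byrow = TRUE))
  grp <- rep(c("AGA", "SGA"), each = 4)
  res <- fda_group_curves(curves, t, grp)
  expect_true(all(abs(res$t_stat) < 1e-8))
  expect_true(all(res$p_value > 0.999))

  # constant offset d with within-group noise sd s: Welch closed form
  set.seed(13)
  d <- 2; s <- 0.3; n <- 6
  eps <- matrix(rnorm(2 * n, 0, s), 2 * n, 1)  # one offset per subject
  curves2 <- rbind(
    t(vapply(eps[1:n], function(e) base + e, numeric(length(t)))),
    t(vapply(eps[(n + 1):(2 * n)], function(e) base + d + e,
             numeric(length(t)))))
  grp2 <- rep(c("A", "B"), each = n)
  res2 <- fda_group_curves(curves2, t, grp2)
  mid <- which.min(abs(res2$grid - 15))
  o1 <- eps[1:n]; o2 <- d + eps[(n + 1):(2 * n)]
  welch <- (mean(o1) - mean(o2)) /
    sqrt(var(o1) / n + var(o2) / n)
  expect_equal(res2$t_stat[mid], welch, tolerance = 1e-6)

  # cubic basis reproduces straight lines exactly
  line <- 1.5 * t - 4
  res3 <- fda_group_curves(rbind(line, line, line, line), t,
                           rep(c("A", "B"), each = 2))
  expect_equal(res3$mean["A", ], 1.5 * res3$grid - 4, tolerance = 1e-8)

  expect_error(fda_group_curves(curves, t, rep("A", 8)), "two groups")
})

test_that("per-subject feature comparison detects generated slope differences", {
  t <- seq(0, 30, by = 0.1)
  mk <- function(m) {
    y <- ifelse(t >= 10, pmin((t - 10) * m, 8), 0)
    y
  }
  set.seed(14)
  curves <- t(vapply(c(rnorm(7, 1.89, 0.1), rnorm(7, 0.88, 0.1)),
                     mk, numeric(length(t))))
  grp <- rep(c("AGA", "SGA"), each = 7)
  res <- group_difference_at(curves, t, grp, feature = "slope",
                             at_time = 12)
  expect_lt(res$p, 0.01)
  expect_gt(res$group_means[["AGA"]], res$group_means[["SGA"]])

  # identical groups: p near 1
  same <- t(vapply(rep(1.5, 8), mk, numeric(length(t))))
  res_same <- group_difference_at(same + matrix(rnorm(8 * length(t), 0, 1e-6),
                                                8),
                                  t, rep(c("A", "B"), each = 4),
                                  feature = "slope", at_time = 12)
  expect_gt(res_same$p, 0.2)

  expect_error(group_difference_at(curves[c(1, 8), ], t, c("A", "B"),
                                   feature = "slope", at_time = 12),
               "2 subjects")
})
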