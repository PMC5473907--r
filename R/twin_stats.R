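#' Friedman rank-sum test on paired (blocked) outcomes
#'
#' Nonparametric test for consistent ordering of k conditions across n
#' blocks (here: twin pairs as blocks, twins ranked within pair).
#' Within-block mid-ranks are summed per condition and
#' \deqn{\chi^2 = \frac{12}{n k (k+1)} \sum_j R_j^2 - 3 n (k+1)}
#' is referred to a chi-squared distribution with k-1 degrees of
#' freedom. With k = 2 and perfectly consistent ordering across all n
#' blocks the statistic equals n (for n = 7: p = 0.008).
#'
#' @param blocks n x k numeric matrix: one row per block, one column
#'   per condition. No missing values allowed.
#' @return List with `chi2`, `df`, `p`, and the per-condition rank sums
#'   `rank_sums`.
#' @examples
#' m <- cbind(rep(1, 7), rep(2, 7))  # twin B always larger
#' friedman_test(m)$p                # 0.00815
#' @export
friedman_test <- function(blocks) {
  blocks <- as.matrix(blocks)
  n <- nrow(blocks); k <- ncol(blocks)
  if (n < 2 || k < 2)
    stop("need at least 2 blocks and 2 conditions", call. = FALSE)
  if (any(!is.finite(blocks)))
    stop("blocks contain missing values", call. = FALSE)
  ranks <- t(apply(blocks, 1, rank))  # mid-ranks for ties
  rj <- colSums(ranks)
  chi2 <- 12 / (n * k * (k + 1)) * sum(rj^2) - 3 * n * (k + 1)
  list(chi2 = chi2, df = k - 1,
       p = stats::pchisq(chi2, df = k - 1, lower.tail = FALSE),
       rank_sums = rj)
}

#' Pair-resampled Spearman correlation for twin data
#'
#' Correlation across subjects with within-pair dependence handled by
#' resampling: in each replicate one twin per pair is selected at
#' random, a Spearman correlation of the selected fetuses' x and y is
#' computed, and after `reps` replicates the median correlation is
#' reported with the p-value of the replicate attaining it. Replicates
#' where x or y is constant have no defined correlation and are
#' excluded (counted in `n_degenerate`).
#'
#' @param pairs data.frame with columns `pair_id` and the two fields, or
#'   a list with `x_a`, `x_b`, `y_a`, `y_b` per pair.
#' @param x_field,y_field Column names of the two quantities (used with
#'   the data.frame form, which must have one row per fetus and a
#'   `pair_id` column).
#' @param reps Number of resampling replicates (default 1000).
#' @param seed RNG seed.
#' @return List: `median_r`, `median_p` (p of the median-r replicate),
#'   `median_of_p`, `r_distribution`, `n_degenerate`.
#' @export
pair_resampled_spearman <- function(pairs, x_field, y_field, reps = 1000,
                                    seed = 1) {
  if (reps < 1) stop("reps must be >= 1", call. = FALSE)
  pid <- unique(pairs$pair_id)
  if (length(pid) < 4) stop("need at least 4 pairs", call. = FALSE)
  xs <- split(pairs[[x_field]], pairs$pair_id)
  ys <- split(pairs[[y_field]], pairs$pair_id)
  if (any(vapply(xs, length, 1L) != 2L))
    stop("each pair must contribute exactly two fetuses", call. = FALSE)
  set.seed(seed)
  r <- p <- rep(NA_real_, reps)
  npair <- length(xs)
  for (i in seq_len(reps)) {
    sel <- sample.int(2, npair, replace = TRUE)
    x <- mapply(function(v, s) v[s], xs, sel)
    y <- mapply(function(v, s) v[s], ys, sel)
    if (length(unique(x)) < 2 || length(unique(y)) < 2) next
    ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                           exact = FALSE))
    r[i] <- unname(ct$estimate); p[i] <- ct$p.value
  }
  ok <- which(is.finite(r))
  if (!length(ok)) stop("all replicates degenerate", call. = FALSE)
  med <- stats::median(r[ok])
  imed <- ok[which.min(abs(r[ok] - med))]
  list(median_r = med, median_p = p[imed],
       median_of_p = stats::median(p[ok]),
       r_distribution = r, n_degenerate = reps - length(ok))
}

#' Linear mixed model with a per-mother random intercept
#'
#' Across-subject regression with the within-pair correlation of twin
#' fetuses absorbed by a random intercept on the mother's (pair) ID.
#' Restricted maximum likelihood estimation; fixed-effect tests are
#' Wald-type t-tests with Satterthwaite degrees of freedom.
#'
#' @param table Per-fetus data.frame.
#' @param response Response column name.
#' @param fixed Character vector of fixed-effect column names.
#' @param group Grouping column for the random intercept (default
#'   `"pair_id"`).
#' @return List: `coefficients` (data.frame: term, estimate, se, df, t,
#'   p), `ranef_sd`, `resid_sd`, `model` (the fitted lmerMod).
#' @export
mixed_model_fit <- function(table, response, fixed, group = "pair_id") {
  miss <- setdiff(c(response, fixed, group), names(table))
  if (length(miss))
    stop(sprintf("missing columns: %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  X <- stats::model.matrix(stats::reformulate(fixed), table)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop(sprintf("collinear fixed effects: %s",
                 paste(aliased, collapse = ", ")), call. = FALSE)
  }
  form <- stats::as.formula(paste(
    response, "~", paste(fixed, collapse = " + "),
    "+ (1 |", group, ")"))
  fit <- lmerTest::lmer(form, data = table, REML = TRUE)
  ct <- stats::coef(summary(fit))
  vc <- lme4::VarCorr(fit)
  list(coefficients = data.frame(
         term = rownames(ct), estimate = ct[, "Estimate"],
         se = ct[, "Std. Error"], df = ct[, "df"],
         t = ct[, "t value"], p = ct[, "Pr(>|t|)"],
         row.names = NULL),
       ranef_sd = attr(vc[[group]], "stddev")[[1]],
       resid_sd = attr(vc, "sc"),
       model = fit)
}

#' Functional-data comparison of group time-activity curves
#'
#' Projects each subject's curve onto a cubic B-spline basis with knots
#' at fixed intervals (default every 2 minutes), evaluates group mean
#' and standard deviation as functions of time on a dense grid, and
#' computes pointwise Welch t-statistic and p-value functions comparing
#' the two group means.
#'
#' @param curves Subjects x time matrix of delta-R2* samples.
#' @param t Common time grid, minutes.
#' @param group Group label per subject (2 levels, >= 2 subjects each).
#' @param knot_spacing Spline knot spacing, minutes (default 2).
#' @param eval_n Number of evaluation grid points (default 151).
#' @return List: `grid` (minutes), `groups`, per-group `mean` and `sd`
#'   matrices (2 x grid), `t_stat`, `p_value`, `df` (pointwise), and
#'   `n` per group.
#' @export
fda_group_curves <- function(curves, t, group, knot_spacing = 2,
                             eval_n = 151) {
  curves <- as.matrix(curves)
  if (ncol(curves) != length(t))
    stop("curve columns must match time grid", call. = FALSE)
  if (max(t) - min(t) < knot_spacing)
    stop("time grid shorter than one knot interval", call. = FALSE)
  levs <- unique(group)
  if (length(levs) != 2 || any(table(group) < 2))
    stop("need two groups with >= 2 curves each", call. = FALSE)
  basis <- bspline_basis(min(t), max(t), knot_spacing)
  X <- basis(t)
  coefs <- t(apply(curves, 1, function(y) {
    cf <- stats::lm.fit(X, y)$coefficients
    cf[is.na(cf)] <- 0
    cf
  }))
  grid <- seq(min(t), max(t), length.out = eval_n)
  B <- basis(grid)
  fitted <- coefs %*% t(B)  # subjects x grid
  g1 <- fitted[group == levs[1], , drop = FALSE]
  g2 <- fitted[group == levs[2], , drop = FALSE]
  m1 <- colMeans(g1); m2 <- colMeans(g2)
  s1 <- apply(g1, 2, stats::sd); s2 <- apply(g2, 2, stats::sd)
  n1 <- nrow(g1); n2 <- nrow(g2)
  se2 <- s1^2 / n1 + s2^2 / n2
  tt <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / (s1^4 / (n1^2 * (n1 - 1)) + s2^4 / (n2^2 * (n2 - 1)))
  pp <- 2 * stats::pt(-abs(tt), df)
  pp[!is.finite(tt)] <- 1; tt[!is.finite(tt)] <- 0
  means <- rbind(m1, m2); sds <- rbind(s1, s2)
  rownames(means) <- rownames(sds) <- levs
  list(grid = grid, groups = levs, mean = means, sd = sds,
       t_stat = tt, p_value = pp, df = df, n = c(n1, n2))
}

#' Two-group comparison of a per-subject curve feature
#'
#' Extracts one scalar feature from each subject's curve — the spline
#' slope at a time point, the smoothed value at a time point, or the
#' end-of-post-epoch mean — and compares the two groups with a Welch
#' (unequal-variance) two-sample t-test.
#'
#' @param curves Subjects x time matrix.
#' @param t Common time grid, minutes.
#' @param group Group label per subject (2 levels).
#' @param feature `"slope"`, `"value"`, or `"end_post_value"`.
#' @param at_time Evaluation time for slope/value features, minutes.
#' @param paradigm An [oxygen_paradigm()] (needed for
#'   `"end_post_value"`).
#' @param knot_spacing Spline knot spacing for slope/value, minutes.
#' @return List: `feature_values` (per subject), `group_means`, `t`,
#'   `df`, `p`.
#' @export
group_difference_at <- function(curves, t, group,
                                feature = c("slope", "value",
                                            "end_post_value"),
                                at_time = NULL, paradigm = NULL,
                                knot_spacing = 2) {
  feature <- match.arg(feature)
  curves <- as.matrix(curves)
  levs <- unique(group)
  if (length(levs) != 2) stop("need exactly two groups", call. = FALSE)
  if (any(table(group) < 2))
    stop("need >= 2 subjects per group for a variance", call. = FALSE)
  vals <- apply(curves, 1, function(y) {
    cv <- list(t = t, mean = y)
    switch(feature,
           slope = curve_slope(cv, at_time, knot_spacing),
           value = curve_value_at(cv, at_time, knot_spacing),
           end_post_value = amplitude_summary(cv, paradigm)$end_post_value)
  })
  wt <- stats::t.test(vals[group == levs[1]], vals[group == levs[2]],
                      var.equal = FALSE)
  gm <- tapply(vals, group, mean)
  list(feature_values = vals, group_means = gm,
       t = unname(wt$statistic), df = unname(wt$parameter),
       p = wt$p.value)
}
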