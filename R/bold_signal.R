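#' Voxel-wise delta-R2* from a BOLD series and baseline map
#'
#' Converts signal intensities to changes in the effective transverse
#' relaxation rate relative to baseline:
#' \deqn{\Delta R_2^*(t) = \ln(S(t)/S_{baseline}) / TE}
#' in s^-1, with the sign convention that delta-R2* increases as
#' oxygenation increases (signal rises, R2* falls). Voxels with
#' nonpositive signal or baseline are flagged invalid and carry NA.
#'
#' @param series A [volume_series()].
#' @param baseline 3D baseline intensity map (from [compute_baseline()]).
#' @param te Echo time in seconds; defaults to `series$te`.
#' @return A list of class `dr2s_series`: `data` (4D delta-R2* array,
#'   s^-1), `frame_times` (minutes), `te`, `baseline`, `valid` (3D
#'   logical).
#' @examples
#' # S / S_baseline = exp(0.35) at TE = 35 ms gives 10 s^-1
#' @export
delta_r2star <- function(series, baseline, te = NULL) {
  stopifnot(inherits(series, "volume_series"))
  if (is.null(te)) te <- series$te
  if (te <= 0) stop("te must be positive", call. = FALSE)
  d <- dim(series$data)
  if (!identical(dim(baseline), d[1:3]))
    stop("baseline grid does not match series", call. = FALSE)
  valid <- is.finite(baseline) & baseline > 0 &
    array(apply(series$data > 0, c(1, 2, 3), all), d[1:3])
  out <- array(NA_real_, d)
  bvec <- as.vector(baseline)
  flat <- matrix(series$data, nrow = prod(d[1:3]), ncol = d[4])
  vidx <- which(as.vector(valid))
  res <- log(flat[vidx, , drop = FALSE] / bvec[vidx]) / te
  oflat <- matrix(out, nrow = prod(d[1:3]), ncol = d[4])
  oflat[vidx, ] <- res
  structure(list(data = array(oflat, d), frame_times = series$frame_times,
                 te = te, baseline = baseline, valid = valid),
            class = "dr2s_series")
}

#' ROI time-activity curve
#'
#' Per-frame mean and standard deviation of delta-R2* over the valid
#' voxels of one ROI.
#'
#' @param d A `dr2s_series` from [delta_r2star()].
#' @param rois An [roi_set()].
#' @param role ROI role name.
#' @return A list of class `tac`: `roi_role`, `t` (minutes), `mean`,
#'   `sd` (s^-1), `n_voxels`.
#' @export
roi_curve <- function(d, rois, role) {
  stopifnot(inherits(d, "dr2s_series"))
  mask <- roi_mask(rois, role) & d$valid
  n <- sum(mask)
  if (n < 1) stop(sprintf("ROI '%s' has no valid voxels", role),
                  call. = FALSE)
  dd <- dim(d$data)
  flat <- matrix(d$data, nrow = prod(dd[1:3]), ncol = dd[4])
  sub <- flat[which(as.vector(mask)), , drop = FALSE]
  structure(list(roi_role = role, t = d$frame_times,
                 mean = colMeans(sub),
                 sd = if (n > 1) apply(sub, 2, stats::sd) else rep(0, dd[4]),
                 n_voxels = n),
            class = "tac")
}

#' @exportS3Method base::print
print.tac <- function(x, ...) {
  cat(sprintf("Time-activity curve '%s': %d voxels, %d frames, peak |dR2*| %.2f /s\n",
              x$roi_role, x$n_voxels, length(x$t), max(abs(x$mean))))
  invisible(x)
}

# Shared cubic B-spline design: knots every `knot_spacing` minutes over
# [t_min, t_max]; returns function of (x, deriv) -> design matrix.
bspline_basis <- function(t_min, t_max, knot_spacing = 2) {
  inner <- seq(t_min, t_max, by = knot_spacing)
  if (abs(inner[length(inner)] - t_max) > 1e-9) inner <- c(inner, t_max)
  knots <- c(rep(t_min, 3), inner, rep(t_max, 3))
  function(x, deriv = 0) {
    splines::splineDesign(knots, pmin(pmax(x, t_min), t_max), ord = 4,
                          derivs = rep(deriv, length(x)),
                          outer.ok = FALSE)
  }
}

# Least-squares projection of sampled curve y(t) onto the basis.
bspline_fit <- function(t, y, knot_spacing = 2) {
  basis <- bspline_basis(min(t), max(t), knot_spacing)
  X <- basis(t)
  coef <- stats::lm.fit(X, y)$coefficients
  coef[is.na(coef)] <- 0
  list(basis = basis, coef = coef,
       predict = function(x, deriv = 0) drop(basis(x, deriv) %*% coef))
}

#' Slope of a time-activity curve at a given time
#'
#' Derivative at `at_time` of the curve's cubic B-spline representation
#' (knots every `knot_spacing` minutes, the same basis used by the
#' functional-data group comparison). The rise slope at the onset of
#' hyperoxia and the fall slope after its end are the group features of
#' interest.
#'
#' @param curve A `tac`, or a list with fields `t` and `mean`.
#' @param at_time Evaluation time, minutes; must lie within the curve
#'   support.
#' @param knot_spacing Spline knot spacing, minutes (default 2).
#' @return Slope in s^-1 per minute.
#' @export
curve_slope <- function(curve, at_time, knot_spacing = 2) {
  t <- curve$t; y <- curve$mean
  if (at_time < min(t) || at_time > max(t))
    stop("at_time outside curve support", call. = FALSE)
  fit <- bspline_fit(t, y, knot_spacing)
  fit$predict(at_time, deriv = 1)
}

#' Value of the spline-smoothed curve at a given time
#' @inheritParams curve_slope
#' @return Smoothed curve value, s^-1.
#' @export
curve_value_at <- function(curve, at_time, knot_spacing = 2) {
  t <- curve$t; y <- curve$mean
  if (at_time < min(t) || at_time > max(t))
    stop("at_time outside curve support", call. = FALSE)
  bspline_fit(t, y, knot_spacing)$predict(at_time)
}

#' Amplitude summaries of a time-activity curve
#'
#' Computes the maximum absolute delta-R2*, the mean over the last two
#' minutes of the hyperoxia epoch (the plateau estimate the study's
#' group amplitudes refer to), and the mean over the final minute of the
#' post-hyperoxia epoch (negative values indicate an undershoot below
#' baseline).
#'
#' @param curve A `tac`.
#' @param paradigm An [oxygen_paradigm()].
#' @return List with `max_abs`, `last2min_mean`, `end_post_value`
#'   (all s^-1).
#' @export
amplitude_summary <- function(curve, paradigm) {
  stopifnot(inherits(paradigm, "oxygen_paradigm"))
  t <- curve$t; y <- curve$mean
  if (max(t) < paradigm$hyperoxia_end - 2)
    stop("curve does not cover the hyperoxia epoch", call. = FALSE)
  w_last2 <- t >= paradigm$hyperoxia_end - 2 & t <= paradigm$hyperoxia_end
  t_end <- min(max(t), paradigm$total_dur)
  w_post <- t >= t_end - 1 & t <= t_end
  list(max_abs = max(abs(y)),
       last2min_mean = mean(y[w_last2]),
       end_post_value = mean(y[w_post]))
}
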