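#' Two-compartment placental blood parameters
#'
#' Placental BOLD contrast arises from maternal blood in the
#' intervillous space and fetal blood in the villous capillaries. The
#' defaults encode the literature values used throughout: maternal
#' volume fraction 40\%, fetal 10\%, ambient oxygen saturations 80\%
#' (maternal) and 60\% (fetal).
#'
#' @param v_m Maternal blood volume fraction (default 0.40).
#' @param v_f Fetal blood volume fraction (default 0.10).
#' @param r2star_relaxivity Relaxivity of deoxyhemoglobin, s^-1 per unit
#'   concentration (calibrated arbitrary unit, default 25).
#' @param sat_m_baseline,sat_f_baseline Baseline oxygen saturations
#'   (defaults 0.80 and 0.60).
#' @param sat_m_plateau,sat_f_plateau Saturations at the hyperoxic
#'   plateau (defaults 0.98 and 0.80); must not fall below baseline.
#' @return A list of class `compartment_params`.
#' @export
compartment_params <- function(v_m = 0.40, v_f = 0.10,
                               r2star_relaxivity = 25,
                               sat_m_baseline = 0.80, sat_f_baseline = 0.60,
                               sat_m_plateau = 0.98, sat_f_plateau = 0.80) {
  if (!(v_f > 0 && v_m > v_f && v_m < 1))
    stop("require 0 < v_f < v_m < 1", call. = FALSE)
  sats <- c(sat_m_baseline, sat_f_baseline, sat_m_plateau, sat_f_plateau)
  if (any(sats <= 0) || any(sats > 1))
    stop("saturations must lie in (0, 1]", call. = FALSE)
  if (sat_m_plateau < sat_m_baseline || sat_f_plateau < sat_f_baseline)
    stop("plateau saturation below baseline", call. = FALSE)
  structure(list(v_m = v_m, v_f = v_f,
                 r2star_relaxivity = r2star_relaxivity,
                 sat_m_baseline = sat_m_baseline,
                 sat_f_baseline = sat_f_baseline,
                 sat_m_plateau = sat_m_plateau,
                 sat_f_plateau = sat_f_plateau),
            class = "compartment_params")
}

#' Ground-truth response parameters for one voxel
#'
#' @param alpha,beta Gamma kernel parameters (minutes scale; both >= 1).
#' @param delta Oxygen arrival delay from hyperoxia onset, minutes.
#' @param c1 Baseline delta-R2* offset, s^-1.
#' @param c2 Plateau amplitude, s^-1.
#' @param convention TTP convention (see [ttp_from_params()]).
#' @param ... Optional recovery-phase fields `alpha_r`, `beta_r`,
#'   `c2_post` (see [response_curve()]).
#' @return A list of class `voxel_truth` including the implied
#'   `ttp_true` in minutes.
#' @export
voxel_truth <- function(alpha, beta, delta, c1 = 0, c2 = 5,
                        convention = "as_printed", ...) {
  if (alpha < 1 || beta < 1 || delta < 0)
    stop("require alpha >= 1, beta >= 1, delta >= 0", call. = FALSE)
  structure(c(list(alpha = alpha, beta = beta, delta = delta,
                   c1 = c1, c2 = c2,
                   ttp_true = ttp_from_params(alpha, beta, delta,
                                              convention),
                   convention = convention),
              list(...)),
            class = "voxel_truth")
}

#' Per-compartment deoxyhemoglobin dynamics
#'
#' Splits a voxel's gamma-convolution oxygenation response into maternal
#' and fetal deoxyhemoglobin concentration changes. Both compartments
#' follow the voxel's kinetics; their magnitudes are proportional to the
#' compartment saturation increments and jointly scaled so that the
#' relaxivity-weighted sum
#' \eqn{-r_2^* (V_F \Delta[dHb_F] + V_M \Delta[dHb_M])}
#' equals the voxel's plateau amplitude C2 at plateau.
#'
#' @param paradigm An [oxygen_paradigm()].
#' @param comp A [compartment_params()].
#' @param response A [voxel_truth()].
#' @param dt Sampling interval, minutes (default 0.1).
#' @return List with `t` (minutes), `dhb_m`, `dhb_f` (concentration
#'   change, <= 0 during hyperoxia), and `dr2s` (the implied delta-R2*
#'   curve, s^-1).
#' @export
simulate_dhb <- function(paradigm, comp, response, dt = 0.1) {
  stopifnot(inherits(comp, "compartment_params"),
            inherits(response, "voxel_truth"))
  t <- seq(0, paradigm$total_dur, by = dt)
  u_m <- comp$sat_m_plateau - comp$sat_m_baseline
  u_f <- comp$sat_f_plateau - comp$sat_f_baseline
  weighted <- comp$r2star_relaxivity * (comp$v_m * u_m + comp$v_f * u_f)
  if (weighted <= 0)
    stop("saturation increments produce no BOLD response", call. = FALSE)
  scale <- response$c2 / weighted
  g <- gamma_step_response(t - paradigm$hyperoxia_start - response$delta,
                           response$alpha, response$beta)
  dhb_m <- -u_m * scale * g
  dhb_f <- -u_f * scale * g
  dr2s <- -comp$r2star_relaxivity *
    (comp$v_f * dhb_f + comp$v_m * dhb_m)
  list(t = t, dhb_m = dhb_m, dhb_f = dhb_f, dr2s = dr2s)
}

#' Simulate one voxel's BOLD intensity time series
#'
#' Inverts the delta-R2* definition: the signal is
#' `S(t) = S_baseline * exp(TE * dR2*(t)) + noise`, where the model
#' delta-R2* follows the gamma-convolution rise during baseline and
#' hyperoxia and a mirrored gamma decay afterwards (see
#' [response_curve()]). Additive Gaussian noise by default; Rician
#' noise available. Intensities that would go nonpositive are clipped
#' at a small positive floor and flagged.
#'
#' @param truth A [voxel_truth()].
#' @param paradigm An [oxygen_paradigm()].
#' @param te Echo time, seconds.
#' @param s_baseline Baseline intensity (> 0).
#' @param noise_sd Noise standard deviation, intensity units.
#' @param t Sample times, minutes; default a uniform TR = 6 s grid.
#' @param noise_model `"gaussian"` (default) or `"rician"`.
#' @return List with `t`, `signal`, `dr2s_model` (noiseless model
#'   curve), `clipped` (logical, any floor clipping).
#' @export
simulate_voxel_series <- function(truth, paradigm, te = 0.035,
                                  s_baseline = 1000, noise_sd = 0,
                                  t = NULL, noise_model = "gaussian") {
  stopifnot(inherits(truth, "voxel_truth"))
  if (s_baseline <= 0) stop("s_baseline must be > 0", call. = FALSE)
  if (is.null(t)) t <- seq(0, paradigm$total_dur, by = 0.1)
  dr2s <- response_curve(truth, t, paradigm)
  s <- s_baseline * exp(te * dr2s)
  if (noise_sd > 0) {
    if (noise_model == "rician") {
      s <- sqrt((s + stats::rnorm(length(t), 0, noise_sd))^2 +
                  stats::rnorm(length(t), 0, noise_sd)^2)
    } else {
      s <- s + stats::rnorm(length(t), 0, noise_sd)
    }
  }
  floor_val <- 1e-6 * s_baseline
  clipped <- any(s < floor_val)
  s <- pmax(s, floor_val)
  list(t = t, signal = s, dr2s_model = dr2s, clipped = clipped)
}

# Solid ellipsoid mask centered at `center` with semi-axes `semi`.
ellipsoid_mask <- function(shape, center, semi) {
  ax <- (seq_len(shape[1]) - center[1]) / semi[1]
  ay <- (seq_len(shape[2]) - center[2]) / semi[2]
  az <- (seq_len(shape[3]) - center[3]) / semi[3]
  outer(outer(ax^2, ay^2, `+`), az^2, `+`) <= 1
}

#' Generate a 4D BOLD phantom with ground-truth TTP structure
#'
#' Builds an ellipsoidal placenta plus two small organ blobs on a voxel
#' grid, assigns each placental voxel gamma-response truth parameters,
#' and synthesizes the BOLD series through the forward signal model.
#' Spatial TTP structure is controlled by `spatial_ttp_field`:
#' `"uniform"` (constant TTP), `"cotyledon"` (smooth lobular variation
#' from superposed radial bumps), or `"pathological_patch"` (a
#' contiguous sub-region whose arrival delay, and hence TTP, is offset
#' by `patch_offset` minutes).
#'
#' @param shape Voxel counts per axis, length 3, each >= 8.
#' @param paradigm An [oxygen_paradigm()].
#' @param spatial_ttp_field One of `"uniform"`, `"cotyledon"`,
#'   `"pathological_patch"`.
#' @param seed RNG seed.
#' @param alpha,beta,delta Base truth parameters of the placental
#'   response.
#' @param c2 Plateau amplitude, s^-1.
#' @param patch_offset Extra arrival delay of the pathological patch,
#'   minutes (default 3).
#' @param tr Repetition time, seconds (default 6).
#' @param te Echo time, seconds (default 0.035).
#' @param s_baseline Baseline intensity.
#' @param noise_sd Intensity noise sd (default 0, noiseless).
#' @return List: `series` ([volume_series()]), `rois` ([roi_set()]),
#'   `truth` (list of 3D maps: alpha, beta, delta, c1, c2, ttp),
#'   `params` (generator arguments).
#' @export
generate_phantom <- function(shape = c(32, 32, 8), paradigm = oxygen_paradigm(),
                             spatial_ttp_field = c("uniform", "cotyledon",
                                                   "pathological_patch"),
                             seed = 1,
                             alpha = 2, beta = 2, delta = 1, c2 = 8,
                             patch_offset = 3, tr = 6, te = 0.035,
                             s_baseline = 1000, noise_sd = 0) {
  spatial_ttp_field <- match.arg(spatial_ttp_field)
  if (length(shape) != 3 || any(shape < 8))
    stop("shape must have >= 8 voxels per axis", call. = FALSE)
  set.seed(seed)
  center <- (shape + 1) / 2
  semi <- pmax(shape * 0.38, 2.5)
  placenta <- ellipsoid_mask(shape, center, semi)
  if (sum(placenta) < 8) stop("ellipsoid does not fit shape", call. = FALSE)
  # two organ blobs tucked in the corners of the grid
  brain <- ellipsoid_mask(shape, pmax(shape * 0.12, 2), pmax(shape * 0.08, 1.2)) &
    !placenta
  liver <- ellipsoid_mask(shape, c(shape[1] * 0.88, shape[2] * 0.12,
                                   center[3]), pmax(shape * 0.08, 1.2)) &
    !placenta
  labels <- array(0L, shape)
  labels[placenta] <- 1L
  labels[brain] <- 2L
  labels[liver] <- 3L
  rois <- roi_set(labels, c(placenta_twinA = 1L, brain_twinA = 2L,
                            liver_twinA = 3L))

  delta_map <- array(delta, shape)
  if (spatial_ttp_field == "cotyledon") {
    # smooth lobular field: superposition of randomly placed bumps
    n_lobes <- 6
    cx <- matrix(stats::runif(n_lobes * 3), n_lobes, 3) %*% diag(shape)
    widths <- stats::runif(n_lobes, 0.15, 0.3) * mean(shape)
    amps <- stats::runif(n_lobes, 0.3, 1.2)
    grid <- as.matrix(expand.grid(x = seq_len(shape[1]),
                                  y = seq_len(shape[2]),
                                  z = seq_len(shape[3])))
    field <- numeric(nrow(grid))
    for (l in seq_len(n_lobes)) {
      d2 <- rowSums((grid - matrix(cx[l, ], nrow(grid), 3,
                                   byrow = TRUE))^2)
      field <- field + amps[l] * exp(-d2 / (2 * widths[l]^2))
    }
    delta_map <- delta_map + array(field, shape)
  } else if (spatial_ttp_field == "pathological_patch") {
    patch <- ellipsoid_mask(shape, center + shape * c(0.15, 0.15, 0),
                            pmax(shape * 0.18, 1.5)) & placenta
    delta_map[patch] <- delta_map[patch] + patch_offset
  }

  truth <- list(
    alpha = array(alpha, shape), beta = array(beta, shape),
    delta = delta_map, c1 = array(0, shape), c2 = array(c2, shape))
  # fetal organs respond with lower amplitude and extra arrival lag
  truth$c2[brain] <- c2 / 6; truth$c2[liver] <- c2 / 2
  truth$delta[brain | liver] <- delta + 1
  truth$ttp <- ttp_from_params(truth$alpha, truth$beta, truth$delta)
  for (nm in names(truth)) truth[[nm]][labels == 0L] <- NA_real_

  t <- seq(0, paradigm$total_dur - 1e-9, by = tr / 60)
  nt <- length(t)
  data <- array(s_baseline, c(shape, nt))
  idx <- which(labels > 0L)
  nvox <- prod(shape)
  for (v in idx) {
    tv <- voxel_truth(truth$alpha[v], truth$beta[v], truth$delta[v],
                      truth$c1[v], truth$c2[v])
    sim <- simulate_voxel_series(tv, paradigm, te, s_baseline,
                                 noise_sd = noise_sd, t = t)
    data[v + nvox * (seq_len(nt) - 1)] <- sim$signal
  }
  series <- volume_series(data, tr = tr, te = te)
  list(series = series, rois = rois, truth = truth,
       params = list(shape = shape, spatial_ttp_field = spatial_ttp_field,
                     seed = seed, alpha = alpha, beta = beta,
                     delta = delta, c2 = c2, patch_offset = patch_offset,
                     tr = tr, te = te, s_baseline = s_baseline,
                     noise_sd = noise_sd))
}
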