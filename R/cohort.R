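#' Specification of a synthetic twin cohort
#'
#' Group-level generating distributions for a monochorionic twin cohort
#' under the hyperoxia paradigm. Amplitude defaults are the reported
#' placental plateau amplitudes (mean over the last 2 min of hyperoxia):
#' 9.83 +/- 4.49 s^-1 for healthy/AGA and 6.55 +/- 3.30 s^-1 for
#' pathological/SGA placentas. Rise-slope defaults are the group slopes
#' at hyperoxia onset, 1.89 (AGA) vs 0.88 (SGA) s^-1/min. Organ plateau
#' amplitudes follow the placenta:liver:brain ratio of roughly 6:3:1.
#'
#' The rise slope of a generated fetus is defined operationally: it is
#' the derivative at hyperoxia onset of the shared cubic B-spline
#' representation of its noiseless placental curve — exactly the
#' quantity [curve_slope()] measures — so slope recovery is unbiased by
#' construction.
#'
#' @param n_pairs Number of twin pairs (default 7).
#' @param assignment Group labels per twin, length 2 (twin A, twin B);
#'   default `c("AGA", "SGA")`.
#' @param amp_mean,amp_sd Named numeric (`AGA`, `SGA`): plateau
#'   amplitude distribution, s^-1.
#' @param slope_mean,slope_sd Named numeric (`AGA`, `SGA`): rise slope
#'   at hyperoxia onset, s^-1/min.
#' @param organ_ratio Amplitude ratio placenta:liver:brain.
#' @param organ_lag Extra oxygen arrival delay of liver and brain,
#'   minutes.
#' @param sga_undershoot Magnitude of the post-hyperoxia undershoot of
#'   SGA fetal organs, s^-1 (their delta-R2* ends below baseline).
#' @param recovery_beta Named numeric (`AGA`, `SGA`): time constant of
#'   the post-hyperoxia mirrored-gamma decay, minutes (SGA organs fall
#'   faster).
#' @param noise_sd Per-sample curve noise, s^-1.
#' @param bw_intercept,bw_slope Birth-weight link: weight (g) =
#'   intercept - slope * TTP (min) + pair effect + residual.
#' @param bw_sga_deficit Additional weight deficit of SGA fetuses, g.
#' @param bw_pair_sd,bw_resid_sd Pair-shared and residual weight sd, g.
#' @param ref_mean,ref_sd Birth-weight reference used to convert weight
#'   to a percentile, g.
#' @param seed Default RNG seed for [generate_cohort()].
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_pairs = 7,
                        assignment = c("AGA", "SGA"),
                        amp_mean = c(AGA = 9.83, SGA = 6.55),
                        amp_sd = c(AGA = 4.49, SGA = 3.30),
                        slope_mean = c(AGA = 1.89, SGA = 0.88),
                        slope_sd = c(AGA = 0.35, SGA = 0.35),
                        organ_ratio = c(placenta = 6, liver = 3, brain = 1),
                        organ_lag = c(liver = 1.0, brain = 1.5),
                        sga_undershoot = 1.5,
                        recovery_beta = c(AGA = 8, SGA = 2.5),
                        noise_sd = 0.5,
                        bw_intercept = 2600, bw_slope = 100,
                        bw_sga_deficit = 450,
                        bw_pair_sd = 150, bw_resid_sd = 100,
                        ref_mean = 2500, ref_sd = 350,
                        seed = 1) {
  if (n_pairs < 1) stop("n_pairs must be >= 1", call. = FALSE)
  if (any(c(amp_sd, slope_sd, noise_sd) < 0))
    stop("standard deviations must be >= 0", call. = FALSE)
  if (any(amp_mean <= 0) || any(slope_mean <= 0))
    stop("amplitudes and slopes must be > 0", call. = FALSE)
  structure(as.list(environment()), class = "cohort_spec")
}

# Characteristics of the unit exponential-saturation curve
# 1 - exp(-(t - onset)/beta), per beta: the spline-measured rise slope
# at hyperoxia onset and the mean over the last 2 min of hyperoxia
# (the amplitude measure the group statistics use).
unit_curve_table <- function(t, paradigm, betas) {
  last2 <- t >= paradigm$hyperoxia_end - 2 & t <= paradigm$hyperoxia_end
  slope <- vapply(betas, function(b) {
    y <- gamma_step_response(t - paradigm$hyperoxia_start, 1, b)
    curve_slope(list(t = t, mean = y), paradigm$hyperoxia_start)
  }, numeric(1))
  plateau <- vapply(betas, function(b)
    mean(gamma_step_response(t[last2] - paradigm$hyperoxia_start, 1, b)),
    numeric(1))
  list(slope = slope, plateau = plateau,
       slope_per_amp = slope / plateau)
}

#' Generate a synthetic twin cohort with ground truth
#'
#' For each fetus, a plateau amplitude and a rise slope are drawn from
#' its group's distributions; the gamma time constant beta is then
#' calibrated (by inverting the precomputed slope-vs-beta relation of
#' the unit-amplitude curve) so that the noiseless placental curve
#' attains exactly the sampled slope at hyperoxia onset under the
#' pipeline's spline slope measure. Since slower rise means larger
#' beta, SGA fetuses automatically get longer true TTP, which then
#' drives the generated birth weights, organ volumes, Doppler grades
#' and pathology findings. Amplitude/slope draws that no admissible
#' beta can satisfy are redrawn (the slope cannot exceed what the
#' sampled amplitude supports).
#'
#' @param spec A [cohort_spec()].
#' @param paradigm An [oxygen_paradigm()].
#' @param seed RNG seed; defaults to `spec$seed`.
#' @param tr Curve sampling interval, seconds (default 6).
#' @return A list of class `twin_cohort`:
#'   `curves` — long data.frame (pair_id, subject_id, twin, group,
#'   organ, t, dr2s);
#'   `records` — per-fetus outcome table (the twin-record table);
#'   `truth` — per fetus-organ generating parameters;
#'   `t` — the common time grid, minutes.
#' @export
generate_cohort <- function(spec, paradigm = oxygen_paradigm(),
                            seed = spec$seed, tr = 6) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(seed)
  t <- seq(0, paradigm$total_dur - 1e-9, by = tr / 60)
  beta_grid <- exp(seq(log(1), log(40), length.out = 200))
  ut <- unit_curve_table(t, paradigm, beta_grid)
  g1 <- ut$slope_per_amp  # decreasing in beta

  organs <- names(spec$organ_ratio)
  ratio <- spec$organ_ratio / spec$organ_ratio[["placenta"]]
  curves <- list(); truth <- list(); records <- list()
  row <- 0L
  for (p in seq_len(spec$n_pairs)) {
    ga_mri <- stats::runif(1, 29, 34)
    scan_to_birth <- stats::runif(1, 0.2, 5.5)
    pair_eff <- stats::rnorm(1, 0, spec$bw_pair_sd)
    for (tw in c("A", "B")) {
      grp <- spec$assignment[if (tw == "A") 1 else 2]
      sid <- sprintf("P%02d%s", p, tw)
      # joint rejection sampling of (amplitude, slope) with admissible beta
      for (try in 1:200) {
        amp <- stats::rnorm(1, spec$amp_mean[[grp]], spec$amp_sd[[grp]])
        slope <- stats::rnorm(1, spec$slope_mean[[grp]],
                              spec$slope_sd[[grp]])
        if (amp < 1 || slope < 0.05) next
        target <- slope / amp
        if (target <= min(g1) || target >= max(g1)) next
        break
      }
      if (try == 200) stop("could not sample admissible fetus parameters",
                           call. = FALSE)
      beta <- stats::approx(g1, beta_grid, xout = target)$y
      ttp_true <- ttp_from_params(1, beta, 0)  # beta - 1 (as printed)
      bw <- spec$bw_intercept - spec$bw_slope * ttp_true + pair_eff -
        (grp == "SGA") * spec$bw_sga_deficit +
        stats::rnorm(1, 0, spec$bw_resid_sd)
      bw <- max(bw, 400)
      pct <- 100 * stats::pnorm(bw, spec$ref_mean, spec$ref_sd)
      brain_vol <- max(150 - 10 * ttp_true + stats::rnorm(1, 0, 8), 40)
      liver_vol <- max(65 - 6 * ttp_true + stats::rnorm(1, 0, 5), 15)
      efw <- max(bw + stats::rnorm(1, 0, 150), 300)
      doppler <- as.integer(pmin(pmax(round(
        ttp_true / 1.5 + stats::rnorm(1, 0, 0.5)), 0), 3))
      n_minor <- min(stats::rpois(1, 0.25 + 0.3 * ttp_true), 3L)
      n_moderate <- stats::rbinom(1, 2, stats::plogis(1.2 * (ttp_true - 2.5)))
      findings <- c(rep("minor", n_minor), rep("moderate", n_moderate))
      score <- pathology_score(pathology_findings(findings))

      last2 <- t >= paradigm$hyperoxia_end - 2 & t <= paradigm$hyperoxia_end
      for (org in organs) {
        delta <- if (org == "placenta") 0 else spec$organ_lag[[org]]
        # scale so the organ's last-2-min mean is exactly ratio * amp
        frac <- mean(gamma_step_response(
          t[last2] - paradigm$hyperoxia_start - delta, 1, beta))
        c2 <- amp * ratio[[org]] / frac
        c2_post <- if (grp == "SGA" && org != "placenta")
          -spec$sga_undershoot else 0
        params <- list(alpha = 1, beta = beta, delta = delta, c1 = 0,
                       c2 = c2, alpha_r = 1,
                       beta_r = spec$recovery_beta[[grp]],
                       c2_post = c2_post)
        y <- response_curve(params, t, paradigm) +
          stats::rnorm(length(t), 0, spec$noise_sd)
        row <- row + 1L
        curves[[row]] <- data.frame(
          pair_id = p, subject_id = sid, twin = tw, group = grp,
          organ = org, t = t, dr2s = y)
        truth[[row]] <- data.frame(
          pair_id = p, subject_id = sid, twin = tw, group = grp,
          organ = org, alpha = 1, beta = beta, delta = delta, c2 = c2,
          c2_post = c2_post, amp_target = amp, slope_target = slope,
          ttp_true = ttp_true)
      }
      records[[sid]] <- data.frame(
        pair_id = p, subject_id = sid, twin_label = tw, group = grp,
        ga_at_mri = ga_mri, scan_to_birth = scan_to_birth,
        birth_weight = bw, weight_percentile = pct, efw = efw,
        doppler_grade = doppler, brain_volume = brain_vol,
        liver_volume = liver_vol,
        findings = paste(findings, collapse = ";"),
        pathology_score = score, ttp_mean = ttp_true)
    }
  }
  structure(list(curves = do.call(rbind, curves),
                 records = do.call(rbind, c(records,
                                            list(make.row.names = FALSE))),
                 truth = do.call(rbind, truth), t = t,
                 paradigm = paradigm, spec = spec, seed = seed),
            class = "twin_cohort")
}

#' @exportS3Method base::print
print.twin_cohort <- function(x, ...) {
  cat(sprintf("Synthetic twin cohort: %d pairs, %d curves (%s)\n",
              x$spec$n_pairs, nrow(x$truth),
              paste(names(x$spec$organ_ratio), collapse = "/")))
  invisible(x)
}

#' Extract a curve matrix for one organ from a cohort
#'
#' @param cohort A `twin_cohort`.
#' @param organ Organ name (default `"placenta"`).
#' @return List with `t`, `curves` (subjects x time matrix), `group`
#'   (per subject), `subject_id`.
#' @export
cohort_curve_matrix <- function(cohort, organ = "placenta") {
  cc <- cohort$curves[cohort$curves$organ == organ, ]
  ids <- unique(cc$subject_id)
  mat <- t(vapply(ids, function(s) cc$dr2s[cc$subject_id == s],
                  numeric(length(cohort$t))))
  grp <- vapply(ids, function(s) cc$group[cc$subject_id == s][1],
                character(1))
  list(t = cohort$t, curves = mat, group = grp, subject_id = ids)
}
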