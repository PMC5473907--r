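---
title: "Modeling placental oxygen delivery with hyperoxia BOLD MRI: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling placental oxygen delivery with hyperoxia BOLD MRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(placentabold)
```

## The measurement and the model

During a maternal hyperoxia challenge (10 min room air, 10 min 100%
oxygen, 10 min room air by default — `oxygen_paradigm()`), placental and
fetal tissue oxygenation rises, deoxyhemoglobin falls, and the BOLD
signal increases. The package quantifies this with the change in the
effective transverse relaxation rate relative to the normoxic baseline,

$$\Delta R_2^*(t) = \ln\!\big(S(t)/S_{\mathrm{baseline}}\big)/TE
\quad [\mathrm{s}^{-1}],$$

signed so that it *increases* with oxygenation. The natural logarithm is
used: it is the relaxometry convention, and it makes the forward signal
model $S = S_{\mathrm{baseline}} e^{TE\,\Delta R_2^*}$ and
`delta_r2star()` exact inverses — a property the test suite checks to
machine precision.

The temporal response of each voxel (or ROI) is modeled as the oxygen
step convolved with a gamma kernel. With the kernel normalized to unit
area, the convolution is the regularized lower incomplete gamma
function, so the fitted curve is

$$R_2^*(t) = C_1 + C_2 \, P\!\big(\alpha,\ (t - t_{\mathrm{on}})/\beta\big),
\qquad t_{\mathrm{on}} = t_{\mathrm{hyperoxia}} + \Delta,$$

monotone nondecreasing with plateau $C_1 + C_2$. Evaluating the
convolution analytically (rather than as a discrete sum) makes $C_2$
identifiable as the plateau amplitude and removes any grid dependence.
The published form of this model shifts the gamma argument *and* the
step by the delay; since both shifts have the identical effect, the
package applies the shift once. The time unit is minutes everywhere
(TE stays in seconds); delays and TTP are measured from hyperoxia
onset, which is the clock on which reported placental TTP values (a few
minutes at most in healthy placentas) live.

**Time-To-Plateau.** The biomarker is $TTP = \Delta + \tau$ with $\tau$
derived from $(\alpha, \beta)$. Two conventions are implemented in
`ttp_from_params()`:

* `as_printed` (default): $\tau = \alpha(\beta - 1)$, the form printed
  with the model;
* `standard_mode`: $\tau = (\alpha - 1)\beta$, the textbook mode of the
  gamma density.

The printed form differs from the textbook mode even though it is
described as the kernel's mode; both are kept because no internal
evidence decides which produced the published maps. The default follows
the printed formula. All ground-truth comparisons in this package use
whichever convention the fit uses, so the choice does not affect the
recovery tests.

## Fitting

`fit_voxel()` minimizes the residual sum of squares over
$(\alpha, \beta, \Delta)$ with box bounds ($\alpha \in [1, 20]$,
$\beta \in [1, 10]$ min, $\Delta \in [0, 9]$ min from onset) and the
linear pair $(C_1, C_2 \ge 0)$ profiled out in closed form (variable
projection). A multiplicative coarse grid over the nonlinear parameters
(6 × 5 × 5 by default), evaluated with the profiled linear solve in one
vectorized pass, supplies the best three starts for an L-BFGS-B
refinement in $(\log\alpha, \log\beta, \Delta)$ with a tight
convergence tolerance. Numerical safeguards worth knowing about:

* candidates whose step-response basis carries essentially no energy
  inside the fit window (response entirely after the window) are
  treated as flat — this keeps the profiled amplitude from exploding on
  near-degenerate bases;
* refined parameters are clamped to the box (the optimizer can return a
  bound violated by one ulp);
* a fit whose amplitude $C_2$ is below 5% of the residual scale is
  flagged `degenerate` and carries no TTP: timing is meaningless for a
  flat curve. Voxel-level failures never raise at map level
  (`fit_map()` marks the voxel invalid).

The fit window defaults to baseline + hyperoxia, because the fitted
step never turns off; the post-hyperoxia epoch is summarized separately
(below). The fit is invariant to joint shifts of the clock and the
paradigm and to amplitude scaling, both covered by tests.

**Identifiability.** Noiseless recovery is exact to better than
0.05 min over a 27-point truth grid spanning $\alpha \in \{1.5,3,6\}$,
$\beta \in \{1.2,2,4\}$, $\Delta \in \{0,2,5\}$ — including corners
whose TTP (up to 23 min) far exceeds the fit window, where only the
toe of the response is observed. With noise, those corners are a
different matter: a Cramér–Rao computation at noise sd 0.5 s⁻¹ and
TR = 6 s gives $\mathrm{sd}(TTP) \gtrsim 1$ min for kinetics as slow as
$\alpha = 2, \beta = 2$, so no least-squares estimator can localize
them to half a minute. The package's noisy-recovery test population is
therefore the placental kinetics its cohort generator produces
($\alpha = 1$, $\beta \in [1.5, 4.5]$ min, $\Delta \in [0,1]$ min,
amplitude ≈ 10 s⁻¹ — TTP in the 0.5–4.5 min range reported for real
placentas), where the measured median error is ≈ 0.1 min.

## Preprocessing

The pipeline assumes motion-corrected, bias-corrected input (those
steps belong to established external tools and are deliberately out of
scope; the generator emits motion-free data satisfying the contract).

* **Outlier frames** — "unexpected average signal change of nearby
  frames" is formalized as a robust z-score: each frame's masked mean
  is compared with the median of a ±2-frame neighborhood (shifted
  inward at the series edges so every frame is judged against the same
  number of neighbors), scaled by 1.4826·MAD of those residuals, and
  flagged above z = 3. Threshold and neighborhood are configuration.
  Flagged frames are dropped and the gap linearly interpolated — drop
  counts are recorded, since the alternative (interpolate in place) is
  equally defensible.
* **Spatial smoothing** — per-frame separable Gaussian, width 5 pixels,
  sigma 1.5, kernel truncated at the stated width and normalized to
  unit sum; with a mask, values inside are renormalized by the smoothed
  mask so no signal bleeds across the ROI boundary. It matches a direct
  triple-loop convolution to 1e−10.
* **Temporal smoothing** — linear interpolation to a uniform grid
  (default step = median TR) followed by a centered moving average of
  10 frames, the middle of the stated 8–12-frame (~1 min) range.
* **Baseline** — voxel-wise mean of unflagged frames acquired before
  hyperoxia onset; at least 3 usable frames are required.

## Curve features and group statistics

ROI time-activity curves carry per-frame mean and sd of valid voxels.
Scalar features — the rise slope at hyperoxia onset, the fall slope
after its end, smoothed values at a time point — are read off a cubic
B-spline representation with knots every 2 minutes, the same basis the
functional-data comparison uses, rather than from finite differences of
noisy samples. The knot spacing bounds the resolvable curvature:
derivative accuracy on smooth gamma curves is ~2% where the curve is
well resolved and degrades near sharp onsets.

The statistical layer mirrors the study design:

* `friedman_test()` — within-pair ranks, $\chi^2 = \frac{12}{nk(k+1)}
  \sum_j R_j^2 - 3n(k+1)$ with $k-1$ df; no tie correction is applied
  (none is described for the study; ties get mid-ranks). For $k=2$ and
  $n=7$ consistent pairs this gives $\chi^2 = 7$, $p = 0.008$; one
  discordant pair gives $p = 0.06$.
* `pair_resampled_spearman()` — one twin per pair drawn uniformly at
  random, Spearman correlation across the selected fetuses, 1000
  replicates; the reported p is the p of the replicate attaining the
  median correlation ("its associated p-value" is ambiguous; keeping r
  and p from the same resample is the design choice here, and the
  median of the p distribution is also returned).
* `mixed_model_fit()` — linear mixed model with a per-mother random
  intercept, REML, Satterthwaite-df Wald-type t tests (via lme4 /
  lmerTest). Covariate sets of interest: gestational age; EFW + TTP;
  Doppler grade + TTP.
* `fda_group_curves()` — least-squares projection of each subject's
  curve onto the shared B-spline basis, group mean and sd as functions
  of time, pointwise Welch t and p. Welch (unequal variance) is used
  for all two-group comparisons since no variant is specified; no
  multiple-testing correction is applied anywhere and all p-values are
  labeled raw.

## The synthetic-data generator

The generator exists so that every pipeline stage can be tested against
known truth. Two levels:

**Phantoms** (`generate_phantom()`): an ellipsoidal placenta plus two
organ blobs on a voxel grid; each voxel gets gamma-response truth
parameters and its BOLD series is synthesized through the forward
signal model ($TE = 35$ ms, $TR = 6$ s, baseline intensity 1000,
additive Gaussian noise; Rician available — at the SNR of interest the
Gaussian approximation is excellent and keeps oracles analytic).
Spatial TTP structure: `uniform`, `cotyledon` (superposed smooth bumps
emulating lobular perfusion domains), or `pathological_patch` (a
contiguous region with arrival delayed by a configurable offset,
+3 min by default — the contrast between healthy and insufficient
placental regions).

**Cohorts** (`generate_cohort()`): monochorionic twin pairs, one AGA
and one SGA fetus per pair by default, 7 pairs. Group parameters are
the study's printed values used as generating distributions: placental
plateau amplitude (mean over the last 2 min of hyperoxia) 9.83 ± 4.49
s⁻¹ (AGA/healthy) vs 6.55 ± 3.30 s⁻¹ (SGA/pathological); rise slope at
hyperoxia onset 1.89 vs 0.88 s⁻¹/min; organ amplitude ratio
placenta:liver:brain = 6:3:1; SGA organs undershoot baseline after
hyperoxia (negative post-phase asymptote, 1.5 s⁻¹) and fall faster
(recovery time constant 2.5 vs 8 min).

Two generator-design points deserve emphasis:

* **The slope parameter is operational.** A fetus's "rise slope" is
  defined as the quantity the pipeline measures — the B-spline
  derivative at hyperoxia onset of its noiseless curve. Given the
  sampled amplitude and slope, the gamma time constant β is calibrated
  by inverting the precomputed slope-per-amplitude relation of the
  unit curve (α = 1 placental kinetics, exponential saturation). Slow
  rise therefore automatically means long TTP, which is exactly the
  physiology the study reports, and slope recovery is unbiased by
  construction. Draws whose slope no admissible β can reach at the
  sampled amplitude (slope > what the amplitude supports) are redrawn;
  this truncates the joint distribution slightly (≈5–10% of draws).
* **Between-subject slope spread** is set to 0.35 s⁻¹/min per group —
  chosen once so cohorts show dispersion comparable to the published
  group error bars while the 1.89 vs 0.88 separation remains a real,
  detectable effect at 7 fetuses per group.
* **The return-to-baseline phase is a modeling choice.** The fitted
  model's step never turns off, and no quantitative post-hyperoxia
  kinetics are published for the placenta; the generator uses a
  mirrored gamma decay with its own rate, and the SGA-organ undershoot
  is implemented as a negative post-phase asymptote.

Downstream outcomes are linked through true TTP: birth weight =
intercept − 100 g/min · TTP + pair-shared intercept (sd 150 g) +
residual (sd 100 g), with an additional 450 g SGA deficit; organ
volumes, estimated fetal weight, Doppler grade and pathology findings
are likewise monotone-in-TTP with noise. The compartment model
(maternal volume fraction 0.40 at 80% baseline saturation, fetal 0.10
at 60%) is used for generation realism only — the fit never sees
compartment parameters, mirroring the phenomenological nature of the
gamma fit.

What the generator does *not* emulate: motion, B0/B1 artifacts,
twin-twin anastomoses, realistic anatomy beyond blobs and lobules, or
any coupling between outcome noise terms. Passing recovery tests on
this synthetic data therefore demonstrates correctness of the
computational pipeline under its stated assumptions, not clinical
performance on patient data.

## Outcome metrics

The 4-point histopathology score implements the printed counting
rules: no findings or one minor → 1; two minors or one moderate → 2;
one minor + one moderate → 3; two moderates or any listed severe
finding → 4. The printed scale assigns *three minor* findings to
score 3 in one sentence and score 4 in the next; the package resolves
the conflict with a maximum rule (score 4) and marks such scores
`extrapolated`. The score is order-invariant and monotone under added
findings (a property test enumerates this). SGA is birth weight at or
*below* the 10th percentile — the boundary is included; the weight
percentile is an input field, since no particular growth reference is
bundled. Birth-weight discordance is $|w_A - w_B| / \max(w_A, w_B)$.

## Problem sizes and runtime choices

The test and acceptance suites use sizes chosen to exercise every code
path at interactive speeds: 8³ volumes for convolution oracles,
10–16³ phantoms for map-level recovery, a 32×32×8 phantom (~1900
placental voxels) for the patch-contrast check, 27-point noiseless and
200-voxel noisy fitting sweeps, and 50 seeded cohort replicates for
the group-slope power check. Larger volumes change nothing about the
algorithms, which are linear in voxel count.

## Known limitations

* TTP is only as identifiable as the fit window allows: responses that
  barely begin within hyperoxia carry little timing information, and
  their noisy fits should be read through the `degenerate`/validity
  flags and the fit report's convergence rate.
* The B-spline slope at a kinked onset (α = 1 truth) is a smoothed
  slope; the generator defines its slope parameter operationally for
  exactly this reason.
* The Friedman statistic without tie correction diverges from
  tie-corrected implementations when blocks contain ties; mid-ranks
  keep it well defined.
* `pair_resampled_spearman` p-values are per-replicate Spearman
  p-values, not corrected for the resampling itself.
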