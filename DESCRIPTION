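Package: placentabold
Title: Quantitative Placental BOLD MRI Analysis Under Maternal Hyperoxia
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for Blood-Oxygenation-Level-Dependent (BOLD)
    MRI of the placenta acquired under a maternal hyperoxia challenge
    paradigm. Computes voxel-wise changes in the effective transverse
    relaxation rate (delta-R2*) relative to a normoxic baseline, fits a
    gamma-convolution oxygenation response model to produce Time-To-Plateau
    (TTP) maps, and provides the twin-pair statistical layer used to relate
    placental TTP to fetal growth outcomes: Friedman rank-sum tests on twin
    blocks, pair-resampled Spearman correlations, linear mixed models with a
    per-mother random intercept, and functional-data comparison of group
    time-activity curves on a cubic B-spline basis. A synthetic-data module
    generates phantoms and twin cohorts with known ground truth so that
    every stage of the pipeline is testable without patient data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    yaml,
    lme4,
    lmerTest,
    splines,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
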