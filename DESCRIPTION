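Package: lvtrajectory
Title: Longitudinal Left-Ventricular Shape-Trajectory Atlases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing ten-year left-ventricular (LV) remodeling from
    point-distribution shape models at two exams. Provides a synthetic cohort
    generator with planted remodeling effects, cross-protocol (GRE to SSFP)
    shape-bias correction by generalized Procrustes alignment, principal
    component analysis and partial least-squares regression, linear-shift
    parallel transport of per-subject remodeling trajectories onto the mean
    baseline shape, a trajectory PCA atlas with z-scored scores, elastic-net
    logistic-regression comparison of atlas scores against mass-volume
    predictors under stratified repeated cross-validation scored by balanced
    accuracy, and reconstruction of per-risk-factor remodeling modes with
    global derived measures and AHA 17-segment regional wall-thickening maps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    mixOmics,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
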