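---
title: "Longitudinal LV shape-trajectory atlases: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Longitudinal LV shape-trajectory atlases: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of the science it implements: the
models, their assumptions, the tunable parameters, the numerical choices,
and what the synthetic-data tests do and do not demonstrate about real
cohort data.

## The problem

Two cardiac MR exams a decade apart give, after segmentation and template
fitting (outside this package's scope), a pair of point-distribution LV
shape models per participant: `P` corresponding 3D points per frame (ED and
ES), identical topology for everyone. The scientific question is how the
*change* in shape over the decade relates to cardiovascular risk factors —
beyond what scalar mass/volume changes capture. Three methodological
obstacles drive the design:

1. **Cross-sectional variation dominates.** Between-subject shape variance
   is much larger than within-subject ten-year change, so naive PCA of all
   shapes mixes the two. The package removes baseline geometry by *parallel
   transport*: each subject's displacement field (follow-up minus baseline)
   is relocated onto the mean baseline shape by **linear shift** — plain
   vector addition in the aligned template frame. Linear shift is the
   correct transport when shapes are close enough to live in one tangent
   space of the shape manifold; ten-year remodeling displacements (a few mm
   against a ~90 mm organ) are comfortably in that regime, which is also
   why no curved-manifold transport is implemented.
2. **The imaging protocol changed between exams.** Baseline GRE cine
   imaging systematically reads smaller cavities and larger mass than
   follow-up SSFP imaging. Uncorrected, this protocol offset would
   masquerade as uniform "remodeling". The correction is learned from
   subjects scanned with both protocols at one session.
3. **Risk factors are correlated with each other and with age/sex.**
   Association strength is assessed by penalized prediction (elastic-net
   logistic regression under cross-validation), and per-factor shape
   effects by multivariate OLS with all other factors as covariates.

## Shape model and derived measures

A shape is flattened as ED block then ES block, each point as (x, y, z),
giving vectors of length `2·P·3` (default 9372). All atlas algebra is
linear algebra on these vectors; concatenating ED and ES means every
component and every mode carries *motion* (ED→ES) information as well as
geometry.

Derived measures are computed from the meshes, not from fitted ellipsoids:
cavity and wall volumes by the divergence theorem on the watertight endo-
and epicardial surfaces (each closed by its basal cap); mass as
`1.05 g/mL × wall volume` at ED — the standard myocardial density
convention, the paper being analysed does not state one; EF and MVR by
their algebraic identities; the long axis as apex-to-mitral-centroid
distance, giving longitudinal shortening and the sphericity volume index
(cavity volume over the volume of the sphere whose diameter is the long
axis — the index is named but not given a formula in the source
literature, so this standard definition is adopted and exposed). Per-point
wall thickness is the corresponding endo–epi point distance; template
correspondence makes this well defined and it is far simpler than
normal-ray casting, at the cost of a slight tangential bias where the wall
is oblique — acceptable because every comparison is *within* the same
correspondence. Relative wall thickness is `2 × inferolateral WT / ED
mid-cavity internal diameter` (an echocardiography-convention analogue;
the mid-cavity diameter is twice the mean distance of mid-band endocardial
points from the long axis).

The AHA 17-segment map assigns every myocardial point by landmark-derived
long-axis height (apical cap below 15 % of the long axis, then thirds) and
circumferential sector (6/6/4 sectors, angle measured from the anterior
reference landmark). Because only landmark-relative geometry enters, the
map is rigid-motion invariant, and segment 17 is defined by the apical-cap
band rather than a separate apex mesh.

The template is a truncated prolate spheroid (endo semi-axes 28.5 × 28.5
× 50 mm, 8 mm ED wall, basal truncation at 40 % of the long semi-axis, ES
= radially 0.68 / longitudinally 0.86 scaled cavity with an 11 mm wall).
These values were chosen once so the template's derived measures sit at
the cohort means of a population study (EDV ≈ 133 mL, EF ≈ 58 %, mass ≈
115 g, MVR ≈ 0.86, RWT ≈ 0.31) and are exposed as arguments. The default
grid (41 circumferential × 19 longitudinal rings + apex + cap center per
surface) realises exactly 1562 points per frame; the split between endo
and epi surfaces is even, a choice the topology file records explicitly
since the source literature does not state one.

## Protocol-bias correction

Training pairs (GRE and SSFP shape models of the same subjects at one
session) are GPA-aligned on their GRE ED frames — the same rigid transform
is applied to the ES frame so contraction is retained, and to the paired
SSFP shape so pairs stay in register. PCA on the aligned GRE vectors
(retaining 95 % of variance by default; the source is silent, and the
result is insensitive between 0.9 and 0.99 because the planted bias's
in-basis part is low-rank) yields K scores per shape. PLSR maps GRE scores
to SSFP scores; the latent-component count is selected by leave-one-out
error over 2…min(20, K) unless fixed.

Two reconstruction choices matter:

* SSFP scores are centered on the **SSFP training mean** and corrected
  shapes are reconstructed around it, so the mean protocol offset —
  including any component orthogonal to the GRE basis — is applied in
  full. Reconstructing around the GRE mean would silently drop the
  out-of-basis part of the bias, and a transmural in/out bias is mostly
  out-of-basis with respect to cross-sectional shape modes; with the SSFP
  mean, a constant planted bias is corrected exactly at zero noise, which
  the unit tests assert.
* The input shape's **out-of-basis residual is preserved**: the correction
  edits only the modeled subspace plus the mean offset, so
  subject-specific detail the training set cannot express is never erased.

Correction is guarded by the protocol flag (applying it to an SSFP shape
is an error), which is what makes accidental double-correction impossible
rather than merely unlikely. GPA uses rigid transforms by default — size
is a remodeling signal and must not be normalised away; a similarity mode
exists for sensitivity analyses. Within `loo_validate()` the PLSR rank is
selected once and held fixed across folds (per-fold reselection would be
an O(n²·ncomp) PLS cascade for negligible benefit), clamped to each fold's
basis size.

## Trajectory atlas and scores

Baselines (bias-corrected where needed) are GPA-aligned; each follow-up
inherits its subject's *baseline* transform rather than being aligned
independently — aligning follow-ups on their own would absorb genuine
longitudinal motion into the pose fit. The displacement is computed in
that common frame, and `transported = mean_baseline + displacement`
exactly (the linear-shift identity, asserted to machine precision). For
cohorts that are already pose-standardised — the synthetic generator's
default, mirroring shape models that arrive in template pose —
`align = FALSE` skips the GPA step; this also makes the cross-sectional
invariance exact: inflating between-subject baseline variance tenfold
changes trajectory scores by less than 10⁻⁶, because baseline geometry
cancels identically in the subtraction. With alignment enabled the
invariance holds only to second order in the per-subject rigid fits.

The atlas is PCA of the transported shapes: components sorted by variance,
sign fixed deterministically (largest-magnitude loading positive) so score
signs are reproducible, full rank retained (downstream consumers
truncate). Scores are z-scored by the training-score standard deviations;
training scores therefore have mean 0 and SD 1 per component, degenerate
(zero-variance) components score 0 with a warning. A published atlas of
this kind reports its first five modes as dimension/sphericity, septal
thickness, concentric, eccentric and functional changes; the variance
fractions printed there (21.9/9.7/8.8/7.9/6.1 %) do not sum to the
in-text 61.6 %, an inconsistency this package does not attempt to
reproduce — synthetic atlases assert internal consistency only.

## Risk labels and the model comparison

Binary factor definitions follow the clinical thresholds: obesity BMI >
30 kg/m²; hypertension diagnosis or SBP > 140 *and* DBP > 90 mmHg (the
conjunction as printed in the source; an `"or"` toggle is provided because
the conjunction is clinically unusual — the divergent case is SBP 150 /
DBP 80); high cholesterol from total > 240, LDL > 160, HDL < 40,
triglycerides > 150 mg/dl combined with **any** by default (the source
chains them with "and", which would label almost no one; the toggle
`chol_rule = "all"` restores the literal reading); diabetes as diagnosis
or impaired fasting glucose; smoking as current smoking at follow-up. A
subject is positive if the factor is present at follow-up, negative if
absent at both exams, excluded otherwise — including factors present at
baseline that resolved by follow-up, which neither label definition
covers.

The comparison design follows the source's description literally: "10-fold
cross validation" with "80 % training / 20 % testing" is not standard
k-fold, so it is implemented as 10 stratified shuffle-splits at 80/20 with
split seeds derived from the master seed and **shared between the two
models**, making the paired fold-wise comparison meaningful. Per split,
elastic-net logistic regression (glmnet) is tuned by randomized search —
50 draws, mixing parameter uniform on {0, 0.1, …, 1}, regularization
strength log-uniform on [10⁻⁴, 10²] — over an inner stratified 5-fold CV
maximizing balanced accuracy; features are standardized on each training
split only. Observations are class-weight balanced in the fit, matching
the balanced-accuracy objective. Models are compared by a paired
two-sided t-test on the 10 fold-wise balanced accuracies (the source marks
significance without naming a test; the paired t-test over common folds is
the natural choice), Bonferroni-corrected across the 8 response variables.
Atlas features are the leading components covering 99 % of trajectory
variance; with isotropic noise in the d ≫ n regime that is most of the
spectrum, which is faithful to the method and harmless to glmnet.

## Remodeling modes

Scores are regressed on baseline age, BSA change, follow-up SBP, DBP, BMI,
HDL, LDL (standardized, so coefficients and reported contrasts are per
SD — the source does not state its contrast units for continuous
predictors), race/ethnicity dummies against the white reference, smoking,
sex, diabetes, statin and hypertension-medication use — OLS fitted
independently per component, which is exactly multivariate OLS with a
common design. "Partitioning the contribution" of a factor is
operationalised as the coefficient-row reconstruction
`Σ_m β_{f,m}·score_sd_m·component_m` with all other predictors at
reference; a test verifies this equals the brute-force difference of
predicted transported shapes at factor = 1 vs 0. Measure deltas apply the
mean trajectory with and without the mode to the mean baseline shape and
express the difference as percent of baseline, mirroring the reporting
convention of longitudinal-variation tables; deltas are masked when they
do not exceed the SEM of the observed per-subject changes. Displacements
are linear in the contrast by construction; measure deltas are linear only
to first order, which is the regime the generator's effect sizes (±15 %)
stay within.

## The synthetic generator

`simulate_cohort()` draws baseline shapes (template + cross-sectional
modes + noise) and follow-ups (baseline + aging drift scaled by the
10-year exam interval + subject-random trajectory modes + per-factor
effect fields for factors present at follow-up + noise). Defaults were
fixed once to emulate the study conditions and are not tuned per test:

* covariate marginals and transitions match the published cohort table
  (age 59.6 ± 9.4 y, 54.3 % female, race mix 41.5/13.4/24.5/20.6 %,
  hypertension-medication 31.2 → 52.8 %, statins 13.4 → 35.1 %, diagnosed
  hypertension 37.8 → 57.1 %, smoking 10.5 → 7.1 %, diabetes severity
  coupled monotonically); monotone conditions gain incident cases by
  one-step Bernoulli transitions, smokers quit and none start;
* the aging drift (endocardium in 0.9 mm, epicardium in 0.45 mm, slight
  ES-only endocardial relaxation) reproduces the published direction and
  scale of ten-year change: EDV −7 %, mass +2 %, MVR +10 % per decade;
* the protocol bias (endo out 1.5 mm, epi in 1.0 mm) gives SSFP larger
  cavities and smaller mass, the documented direction;
* effect fields per factor are small transmural/scale fields keeping
  derived-measure deltas within ±15 % — inside the small-deformation
  regime that justifies linear-shift transport;
* measurement noise defaults to 0.4 mm per coordinate per exam. Where a
  test specifies a signal-to-noise ratio of 1, the noise SD is set so the
  expected noise norm of a trajectory equals the planted field norm.

Everything is reproducible from `(config, seed)`; the planted truth (mode
scores, effect fields, presence indicators) is returned for
parameter-recovery tests but never read by the pipeline.

**What passing tests show — and what they do not.** The generator is
linear-Gaussian around one template: real cohorts have non-Gaussian shape
variation, segmentation failures, correspondence errors, non-constant
protocol bias (the published validation trained on ~500 dual-protocol
scans precisely because the bias varies by subject), and risk-factor
effects that are neither additive nor constant across the population.
Recovery of planted modes therefore validates the *pipeline's
correctness*, not the clinical effect sizes; the package deliberately does
not claim to reproduce published balanced accuracies or per-factor delta
tables, which depend on restricted cohort data.

## Numerical choices and problem sizes

GPA converges when the mean ED shape moves less than 10⁻⁶ mm (cap 100
iterations; 2–5 suffice in practice) and rejects rank-deficient point
sets. PCA is computed by SVD of the centered data matrix (n ≪ d, so the
n-sided factorisation is the cheap one). Degenerate elastic-net folds
(single-class inner folds) are dropped from the tuning average;
rank-deficient OLS designs are an error naming the collinear columns
rather than a silent pivot. Exclusion flows are integer arithmetic and
validated to never go negative.

The shipped tests and the acceptance script run the simulation-based
checks on a 200-points-per-surface template (P = 400, d = 2400) with the
analysis-scale cohort sizes (n = 500 for atlas recovery, association and
mode recovery; n = 100 pairs for leave-one-out), which keeps the full
suite within a few minutes while leaving every tolerance unchanged;
geometry checks also run at the full 1562-point default. Known
limitations: two timepoints only (no within-decade dynamics), linear
transport only, no survival or outcome modeling, and no attempt at
realistic race/ethnicity effect calibration in the generator.
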