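---
title: "Radiomics and ctDNA in longitudinal cohorts: models and methods"
author: "ctradiomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Radiomics and ctDNA in longitudinal cohorts: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctradiomics)
```

This vignette is the package's account of its statistical machinery: the
models and their assumptions, the tunable parameters, what the
synthetic-data generator does and does not emulate, the numerical choices,
and the design decisions taken where the design was genuinely open.

## The setting

A small cohort of patients (tens, not hundreds) is followed through
treatment with serial CT imaging and blood sampling. Each imaging visit
yields a tracked lesion volume and a vector of radiomic texture features;
each blood draw yields a ctDNA mutant allele fraction (maf, a fraction in
(0, 1]) and usually a serum LDH measurement. Three structural facts
dominate the analysis:

1. **Clustering.** Visits are nested in patients; responses within a
   patient are correlated. Every model is a random-intercept linear mixed
   model with the patient as the grouping factor.
2. **Volume confounding.** Lesion volume drives log(maf), and essentially
   all texture features correlate with volume. Any claim that
   heterogeneity features predict ctDNA must survive adjustment for
   volume.
3. **Multiplicity with correlated features.** Dozens of intercorrelated
   features are screened; naive error rates are meaningless without
   calibration. Spiked-in random predictors act as negative controls both
   for the FDR screen and for the selection stopping rules.

## Feature extraction

Extraction follows the common LIFEx-style configuration. Intensities are
resampled to 1 mm isotropic voxels (trilinear; the mask trilinear then
re-binarized at 0.5), discretized over the absolute range [-400, 400] HU
into 128 gray levels — 32 levels for the zone-length family, following
IBSI advice for that family — with out-of-range values clipped into the
edge bins. Bin index is `floor((v - lo)/w) + 1` with `w = (hi - lo)/n`;
the upper bound maps into the top bin.

Texture matrices pool the 13 unique 3D directions at distance 1: the
co-occurrence matrix is symmetrized and features computed on the pooled
normalized matrix (a deterministic, oracle-checkable dialect; some tools
instead average per-direction features), runs are pooled into one
run-length matrix, and zones are 26-connected components of equal gray
level. Degenerate cases have fixed conventions: GLCM Correlation with a
single occupied gray level is `NA`; NGLDM Coarseness with a zero
denominator (constant region) is capped at 10^6; NGLDM Busyness of a
constant region is 0. Sphericity uses the exposed voxel-face surface area
rather than a mesh, which overestimates surface area slightly and is
documented as approximate. Lesions under 1 cm³ (evaluated on the native
grid, before resampling) are excluded unless explicitly overridden. The
canonical 39-name set is `radiomic_feature_names()`; `extract_all()`
computes a slight superset (Min, Max) flagged via the `in_default_set`
attribute, since the canonical membership of first-order extremes varies
between tools.

Every texture feature is verified against an independent brute-force
enumeration oracle (explicit pair/run/zone/neighborhood loops) to 1e-9 on
hundreds of random small volumes, and the run/zone matrices are checked to
conserve voxel counts.

## Cohort assembly

maf at an imaging date is linearly interpolated between the two bracketing
blood samples, on the maf scale (the natural reading of "linear
interpolation"; interpolating log(maf) instead would change values by
< a few percent at typical sampling gaps). Outside the sampled range the
nearest sample is carried over and flagged as extrapolated — our rule,
chosen over refusing to extrapolate so that boundary visits are not lost.
Where both assays exist on a date, the sWGS tumor fraction is used at or
above its 3% limit of detection and TAm-Seq below it; a below-LOD sWGS
value without TAm-Seq backup is kept but flagged. maf = 0 is floored at
1e-6 (configurable) so the log response is finite. Assay agreement is
summarized by Lin's concordance correlation coefficient with its original
population-moment estimator; the 95% CI uses the Fisher z-transform, the
standard asymptotic form (the CI method for this estimator is a
convention, not a derivation from data).

## The mixed-model core

All models are Gaussian random-intercept models
`y = X beta + b_g + e`, `b_g ~ N(0, sigma2_patient)`,
`e ~ N(0, sigma2_resid)`. The fitter profiles beta and the residual
variance out of the (restricted) likelihood and optimizes the variance
ratio `theta = sigma2_patient/sigma2_resid` on the log scale by
golden-section search (compiled; tolerance 1e-9 on log theta, explicit
comparison against the theta = 0 boundary). Per-group Woodbury identities
make each objective evaluation closed-form, which keeps a fit around a
millisecond — the Monte-Carlo stages run hundreds of thousands of fits.
The implementation is cross-checked against lme4/lmerTest in the test
suite (coefficients, variance components, likelihoods, and Satterthwaite
degrees of freedom agree to displayed precision).

Wald t statistics use Satterthwaite denominator degrees of freedom
(numeric gradients of the coefficient variance with respect to the
variance components against the observed REML information); at the
boundary `theta = 0` the residual df `n - p` applies. Marginal R² is the
fixed-effects variance share
`Var(X beta) / (Var(X beta) + sigma2_patient + sigma2_resid)`.
Likelihood-ratio tests compare nested fixed-effect designs under ML only;
passing REML fits is an error because restricted likelihoods are not
comparable across fixed designs.

The robust companion fit is an iteratively reweighted scheme with Huber
weights (c = 1.345) on scaled conditional residuals — a deliberate
simplification of full robust mixed-model estimators, adequate as a
sensitivity analysis: on clean data it tracks REML within sampling error,
and a gross response outlier moves the robust estimate by a small fraction
of the non-robust shift.

## Screening, selection and the spike-in logic

Features are transformed before modelling (identity, `log f`,
`log(a + f)` or `log(log f + a)`, optionally z-scored with stored
constants). Transform choice is configuration, not automated search: a
registry maps feature names to transforms, defaulting to identity with
log-scale entries for volume-like quantities; the registry is exposed so
an analyst can mirror choices made by inspection. The same stored
constants standardize any future data (training constants are never
refitted at evaluation).

The unadjusted screen fits `log(maf) ~ feature` per feature (volume
itself participates as a feature); the adjusted screen fits
`log(maf) ~ feature + log(volume)` and additionally tests each feature by
LRT against the volume-only model. One hundred spiked random predictors —
half independent, half with a patient-level variance share matching the
feature ICC — join the BH adjustment, which is applied to the combined
real + random p-value set, so the negative controls compete in the same
multiplicity correction they calibrate. Under a global-null generator the
fraction of screens with any BH discovery at 5% sits near 5%, which the
acceptance suite verifies over 200 replicate screens.

The clustered-data LASSO exploits the fact that, at fixed variance
components, the penalized random-intercept problem is an ordinary lasso on
GLS-whitened data: each patient block is whitened by
`(I + theta J)^{-1/2}` in closed form, glmnet solves the whitened problem
(intercept carried as an unpenalized whitened column), and the variance
ratio is re-estimated from the active set and iterated to a fixed point
per lambda (relative tolerance 1e-4 on theta; re-estimation is skipped
when the active set approaches saturation). The lambda grid is 100
log-spaced points from just above the empty-set lambda down by a factor
1000. The selected lambda is the smallest whose active set contains no
random predictor — the negative-control analogue of choosing the penalty
by noise entry. Stepwise selection greedily adds the predictor maximizing
marginal R² (ML fits by default; REML is configurable — the likelihood
used for R² comparison is a convention the data cannot settle), halting
when the best candidate is a random predictor or the improvement falls
below 1e-4, with backward drops allowed after each addition and ties
broken by feature name for determinism.

## The signature and the Monte-Carlo null test

The radiomics signature is the first principal axis of the five features
with the smallest volume-adjusted LRT p-values, computed on the
correlation scale (columns transformed and z-scored first). Its loading
vector has unit Euclidean norm; the sign — arbitrary for an eigenvector —
is fixed by positive correlation with the training response, for which
|log(maf)| is the display convention (maf < 1 makes log(maf) negative
throughout, so |log(maf)| is simply its negation; model fitting uses
log(maf) and is sign-invariant). A fitted signature serializes to JSON
(names, transforms, constants, loadings) and can be applied unchanged to
new feature tables.

The null reference test asks whether the five-feature model (or the
signature built from it) beats lesion volume by more than selection bias
alone would produce. Null feature sets are drawn Gaussian with the
covariance estimated from the transformed real features jointly with
log-volume (eigenvalues clipped at 1e-10 for positive
semi-definiteness), *conditionally on the observed volume column*: each
null feature keeps its estimated volume correlation while the response —
which never enters the generator — has zero population correlation with
it by construction. This population-level reading of "zero correlation"
keeps the null datasets exchangeable with a no-signal real dataset;
sample-level orthogonalization would not. Patient-level dependence can be
mixed in at a configured ICC, splitting the conditional covariance
between patient and visit levels. Crucially, the top-5 selection is
re-run inside every null dataset, so the null distribution carries the
same selection bias as the real statistic; disabling re-selection is
refused unless explicitly overridden, because it biases the test
anti-conservatively. Empirical exceedance probabilities use the add-one
rule `(1 + #{null >= real}) / (N + 1)` and are never exactly zero. The
study-scale default is 2500 datasets of 38 features; the test suite runs
200–500, where calibration (empirical p uniform under the null, KS at 1%)
and power (p < 0.01 for a strongly planted five-feature signal) are both
verified.

## Association models

The triangle log(maf)–LDH–signature is fitted pairwise with linear and
quadratic random-intercept models (the quadratic term on the centered
predictor). Model form is chosen by a residual trend statistic: the
correlation of the linear fit's standardized residuals with the squared
centered fitted values, with the quadratic form kept above a threshold of
0.1 — an automated stand-in for choosing the form from the
residual-vs-fitted plot, logged and overridable. Pairs with marginal R²
under 0.1 are flagged near-independent; LDH values are flagged against an
upper limit of normal of 246 U/L. Transforms for the triangle come from
the same registry as screening.

## The synthetic-data generator

`generate_cohort()` emulates the study conditions the analysis assumes:
15 patients with 1–12 visits each (Poisson-shaped counts averaging
70/15 ≈ 4.7), imaging roughly 2-monthly (log-normal intervals, median
60 days), lesion volumes log-normal around ~20 mL. Features plus latent
log-volume are multivariate Gaussian via a Cholesky factor of a target
correlation matrix — by default a single-factor structure (loadings
cycling over 0.4–0.85, volume loading 0.8) giving the strong feature
intercorrelation and volume correlation the adjusted analyses must
untangle — with patient dependence added as a shared per-patient
component scaled to a feature ICC of 0.3. The response is
`log(maf) = beta0 + beta_volume log(volume) + b_patient + eps` with
defaults `beta0 = -11`, `beta_volume = 0.8`, residual sd 0.8 and response
ICC 0.4 (the observed ICC the original setting matched is not public, so
it is a config default, not a constant), clipped into (0, 1] via a 1e-6
floor so the log is always defined. An optional `beta_features` vector
plants a genuine feature signal on the latent standardized scale — the
hook used by the power, recovery and association tests. LDH is quadratic
in log(maf) (coefficients (800, 180, 12), noise sd 160 U/L — chosen once
so the maf–LDH association lands in the "moderate" range rather than
deterministic). Blood draws are offset from visits by a signed
discretized log-normal interval with exact median 10 days; a log-normal
cannot also match an asymmetric interquartile range of (4, 34), so the
spread parameter is calibrated to the quartile ratio
(`sigma = log(34/4)/(2 * 0.6745)`), giving quartiles near (3.4, 29).
Feature columns are emitted on natural scales by inverting each feature's
registered transform, so the analysis-side transforms recover the target
correlation structure exactly.

What the generator does **not** emulate: real CT anatomy or scanner
physics (phantom textures are constant, checkerboard or correlated
noise), informative visit schedules, missing data, assay-specific error
structure, non-Gaussian feature tails, or treatment effects. Passing
tests therefore demonstrate that the *procedures* are correct and
calibrated under the assumed structure — not that any particular clinical
dataset satisfies that structure.

## Numerical choices and problem sizes

Variance ratios are optimized on the log scale over `[e^-30, e^15]` with
an explicit boundary comparison at zero; residual variances are floored at
1e-12; PCA refuses an ambiguous first axis (eigengap < 1e-8); the robust
covariance estimator shrinks its scatter toward the diagonal when `n <= p`
or the scatter degenerates, with the shrinkage intensity reported. The
test suite sizes its simulations for a desk run: 500 oracle volumes at
up to 6×6×6 voxels, 200 coverage and 200 FDR-calibration replicates at
the cohort scale, 100 selection-recovery replicates, 40 null-test
calibration replicates of 200 null datasets each, and a 500-dataset power
run; the full suite completes in a few minutes on one core.

## Known limitations

- The GLCM/GLRLM pooling convention and the voxel-face surface area are
  dialect choices; bit-exact agreement with any specific extraction tool
  is not claimed.
- The robust fit is a Huber reweighting, not a full robust
  variance-component estimator; it is reported side-by-side with REML,
  never merged.
- The LASSO path refits variance components per lambda rather than
  jointly optimizing the penalized likelihood; active sets can differ
  near ties from a fully joint solver.
- Satterthwaite df relies on numeric second derivatives; at extreme
  variance ratios it falls back to residual df.
- The null test presumes the transformed features are reasonably
  Gaussian given volume; heavy-tailed features would call for a
  rank-based variant that is not implemented.
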