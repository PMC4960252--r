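---
title: "Variable selection for untargeted LC-MS metabolomics: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Variable selection for untargeted LC-MS metabolomics: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Untargeted LC-MS metabolic fingerprinting produces tables with hundreds to
thousands of features (mass/retention-time pairs with per-sample abundances)
measured on a few dozen to a few hundred samples. When the goal is to find
the features that discriminate two clinical groups — candidate biomarkers —
the analyst faces a "small n, large p", strongly multicollinear selection
problem. `metabselect` implements and compares three standard routes through
it on a single table:

1. **OPLS-DA with VIP**: a supervised latent-variable model whose
   orthogonal-signal-correction (OSC) filter strips class-uncorrelated
   variation before a single predictive component is fitted; features are
   ranked by variable importance in projection (VIP) and selected at
   VIP > 1.
2. **FDR-prefiltered OPLS-DA**: per-feature two-group tests with
   Benjamini–Hochberg correction select a significant subset first; OPLS-DA
   with VIP then runs on that subset only.
3. **LASSO penalized logistic regression**: L1-penalized maximum likelihood
   performs estimation and selection jointly; the stability of each selected
   feature is quantified by its inclusion frequency over bootstrap
   resamples.

The package also ships the upstream plumbing these methods assume — pooled-QC
quality-assurance filtration, unit-variance/Pareto scaling, PCA screening
with Hotelling's T² limits — and a synthetic-data generator with known ground
truth, because public raw data for studies of this design are rarely
available and methodological claims need a truth to be scored against.

# Models and procedures

## QA filtration

Three rules, applied in order, with "detected" meaning non-missing after
sentinel handling (vendor exports write 0 or blank for non-detects):

* **QC presence**: keep features detected in ≥ 50% of the pooled-QC
  injections (inclusive).
* **QC repeatability**: keep features whose coefficient of variation
  (sd/mean, n−1 denominator, raw intensity scale) across QC injections is
  strictly < 20%. Features with fewer than two observed QC values have an
  undefined CV and are removed.
* **Group presence**: keep features detected in ≥ 80% of the samples of at
  least one study group (inclusive); QCs are excluded here.

The CV is computed on raw rather than log intensities — the convention of
the QC-based QA literature the thresholds come from. The three rules are
mutually order-independent (presence fractions and QC values are unchanged
by the other filters), which the suite asserts; the canonical order above is
retained for log readability.

Missing cells that survive filtration are left-censored non-detects, so for
modeling they are imputed by half the feature's minimum observed value — the
usual limit-of-detection convention. Imputation is flagged and reversible
(`unimpute_lod()`); the univariate tests and models run on the imputed
table.

## Scaling

Both scalings centre each feature and divide by a dispersion-based factor:
the standard deviation (unit variance, UV) or its square root (Pareto). UV
makes every feature equally important; Pareto compresses high-variance
features less, so large fold changes remain partially dominant. Scaler
statistics are fitted on study samples only — QC injections replicate a
single pooled sample and would bias the dispersion estimates downward. In
cross-validation the scaler is refitted inside each training fold by default
(leakage-safe); `refit_scaler_per_fold = FALSE` mimics software that scales
once on the full matrix before cross-validating. This choice can shift Q²
slightly; it does not affect the fitted model itself.

## Univariate testing and FDR

Per feature, the test is chosen by the classical gatekeeper logic: if
Shapiro–Wilk accepts normality in both groups (p > 0.05), Levene's test
(median-centred, i.e. Brown–Forsythe, chosen for robustness) decides between
the pooled-variance Student t and Welch's t; otherwise the Mann–Whitney U
test is used (exact for small samples without ties, tie-corrected normal
approximation otherwise). Constant features get p = 1 with a warning;
groups too small for Shapiro–Wilk fall back to Mann–Whitney. The gate level
and the significance threshold are both 0.05 unless overridden: the q < 0.05
convention is assumed since only "significant after FDR correction" is
conventional usage. Benjamini–Hochberg adjustment is implemented as the
step-up `q_(i) = min_{j≥i} p_(j)·m/j`, capped at 1; its rejection set
coincides with the classical "largest k with p_(k) ≤ kα/m" rule, which the
suite verifies by brute force. The tests run on raw filtered intensities:
both t-variants and Mann–Whitney are exactly invariant under the per-feature
affine maps that UV/Pareto scaling apply, so their order relative to scaling
is immaterial (asserted as a property).

## OPLS-DA

For class codes y ∈ {+1, −1} (lexicographic group order, first level → −1)
and a scaled matrix X, the predictive weight is `w ∝ X'y`, normalised. Each
of the K orthogonal components is built against the current matrix:
`t = Xw`, `p = X't/(t't)`, `w_orth ∝ p − (w'p)w`, `t_orth = X w_orth`,
`p_orth = X't_orth/(t_orth't_orth)`, then X is deflated by
`t_orth p_orth'`. The final predictive component on the filtered matrix
gives `t = Xw`, `c = y't/(t't)`, and `R²Y = 1 − ‖y − tc‖²/‖y − ȳ‖²`. The
predictive weight is computed once from the initial scaled matrix; each
orthogonal component is then extracted against the current deflated matrix.
For the single-predictive-component architecture used here this spans the
same predictive direction as formulations that re-derive the weight after
each deflation, and it is the recursion the test suite checks step by step
against an independently coded oracle.

Defaults: 1 predictive + 1 orthogonal component. Component counts are not
derivable from the data contract, so they are configurable; one orthogonal
component is the standard minimal OSC architecture for a two-class model.

**VIP** is computed from the predictive component only (post-OSC):
`VIP_j = √p·|w_j|` with ‖w‖ = 1, hence mean(VIP²) = 1 identically and
VIP > 1 reads as "above-average influence". Restricting VIP to the
predictive component matches the stated purpose of the OSC filter —
selection should reflect class-predictive variation, not the structured
noise the filter removed.

**Q²** comes from stratified 7-fold cross-validation of the whole
scale-then-fit pipeline; held-out samples are deflated by the training
orthogonal components before scoring, and `Q² = 1 − PRESS/SS` accumulates
`SS = Σ(y − ȳ_train)²` over folds.

**PCA screening**: scores from the SVD with a fixed sign convention (the
largest-magnitude loading element of each component is positive, making
runs backend-independent); Hotelling's
`T²_i = Σ_a t²_ia/λ_a` against the F-based limit
`A(n−1)(n+1)/(n(n−A))·F_{A,n−A}(0.95)`. Outlier removal is an explicit
opt-in, single-pass stage (fit once, drop flagged samples once).

## LASSO penalized logistic regression

On standardized covariates (mean 0, sd 1) and y ∈ {0, 1}, the package
minimizes `−lnL(y; β₀, β) + λΣ_j|β_j|` with the intercept unpenalized —
the additive log-likelihood-plus-penalty form, with no 1/n factor; λ is
therefore on the scale of the summed score, and
`λ_max = max_j |x_j'(y − ȳ)|` is the exact knot above which the active set
is empty (KKT at β = 0). The solver is cyclic coordinate descent with
soft-thresholding on the iteratively reweighted quadratic approximation,
warm-started along a 100-point log-spaced grid from λ_max down to
10⁻³λ_max, with a step-halving safeguard that keeps the exact objective
non-increasing (asserted per iteration in the suite). Convergence is
declared when the largest coefficient change falls below 1e−8; KKT
residuals along fitted paths are verified to 1e−6.

λ is selected at the minimum-AIC fit with
`AIC = −2lnL + 2(|active| + 1)` — the standard LASSO degrees-of-freedom
estimator plus the intercept. A cross-validation rule ("5-fold CV at
minimum AIC") conflates two selectors; the package makes full-data AIC the
default and offers stratified 5-fold held-out deviance (`cv_deviance`,
per-fold re-standardization) as the documented alternative. AIC ties break
toward the larger λ — the sparser model — as the conservative convention.

**Bootstrap stability**: the entire model development (re-standardization,
λ re-selection, fit) is repeated on resamples drawn with replacement,
stratified by group so no resample loses a class; per-resample
standardization follows from the problem definition, which requires
standardized covariates. A feature constant within a resample is dropped
from that resample and counted as not selected. Reproducibility is the
percentage of resamples (default 1000) in which a feature entered the
model. The reported selection is the full-data active set annotated with
reproducibility; low-reproducibility members are flagged, never removed.

## The comparison

`compare_selections()` counts all seven Venn regions of the three selected
sets and their consensus. The headline comparison uses the UV-scaled OPLS
selections (with Pareto reported alongside), since UV is the scaling under
which the OPLS approaches select most broadly and is the conventional
headline in three-way comparisons of this design; LASSO appears once, as it
standardizes internally and is scaling-free.

# The synthetic-data generator

`simulate_study()` emulates the data-generating structure the QA filters and
models assume, with every parameter a design field:

* two balanced study groups (default 50 + 50) and 8 pooled-QC injections;
* per-feature baseline log2-abundances ~ N(log2(10⁵), 2²) — a wide
  dynamic range;
* 10 of 500 features planted as discriminating at ±1 log2 unit (a 2-fold
  change, random sign);
* biological variation from a block factor model: blocks of 10 consecutive
  features share a per-sample factor giving within-block correlation 0.6 —
  the multicollinearity (adduct/fragment/pathway groups) that
  distinguishes LASSO's behaviour from the PLS family; per-feature
  biological dispersion is drawn lognormal (log-sd 0.4) around a 30%
  median CV, because heterogeneous feature variances are exactly the
  regime where UV and Pareto scaling genuinely disagree;
* analytical noise at 15% CV, the level a well-behaved LC-MS sequence
  holds in QCs;
* QC injections as the pooled sample: the per-feature mean of the study
  samples' expected intensities plus analytical noise only;
* left-censoring at the per-feature 5% intensity quantile (missing not at
  random), the mechanism the presence filters implicitly address.

What it does **not** emulate: chromatographic drift and batch effects,
isotope/adduct redundancy as structured duplicates, or heavy-tailed
single-sample artefacts. Passing recovery tests on this generator shows the
selection machinery behaves as designed under its assumptions; it does not
certify performance on real data violating them.

Default sample sizes and effect sizes are chosen so that the planted signal
is clearly but not trivially recoverable (univariate BH recall ≥ 80% at the
defaults, asserted as the calibration anchor); the suite's heavier
simulations use 20 replicate seeds and a 200-resample bootstrap, sizes at
which every documented contrast is decided with margin.

# Numerical choices and degenerate inputs

* Standard deviations use the n−1 denominator throughout.
* Zero-variance features are a hard error at scaling/standardization time,
  with ids listed; upstream, constant-in-resample features are silently
  dropped per resample (bootstrap) as documented.
* Coefficients below 1e−12 in absolute value are clamped to exact zero when
  forming the active set: a coordinate sitting exactly on its KKT knot can
  otherwise pick up one-ulp noise.
* BH q-values are guarded with `pmax(q, p)` against one-ulp rounding in
  `p·m/j`.
* Tie-breaks: minimum-AIC ties choose the larger λ; the strict inequalities
  are as printed in the thresholds (CV < 20%, VIP > 1, q < 0.05; presence
  fractions inclusive).
* Stratified fold assignment reshuffles once if a training fold lacks a
  class, then errors.
* Empty QA output is allowed (0-feature table); modeling entry points
  error only when they genuinely need p ≥ 1.
* All seeded internals save and restore the caller's RNG state.

# Known limitations

* Single predictive component only (two-class designs); no multi-class
  OPLS-DA.
* No permutation p-values / CV-ANOVA for the OPLS models.
* No ridge or elastic-net alternative (the `penalty_weights` field keeps
  the interface open, but grouped selection of correlated predictors is out
  of scope).
* No batch/drift correction; the generator correspondingly does not
  simulate drift.
* Reported Q² depends mildly on the fold-scaling convention (see Scaling);
  both conventions are exposed.
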