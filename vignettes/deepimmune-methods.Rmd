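---
title: "Methods: Deep-immune scoring, stroma-CD3 density, and survival validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Deep-immune scoring, stroma-CD3 density, and survival validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(deepimmune)
```

## The model

A whole-slide image is reduced to a patch grid: patches of side
`patch_size_px` (default 224 px at 20×) anchored every `stride_px` pixels
(default 112 px, i.e. 50% overlap), incomplete margins dropped. A pluggable
classifier assigns each patch a probability vector over nine tissue classes
(adipose, background, debris, lymphocyte aggregates, mucus, muscle, normal
mucosa, stroma, tumor epithelium — fixed alphabetical order everywhere), and
the segmentation takes each cell's maximum-probability class, ties broken
deterministically toward the lower class index.

Three per-patient quantities follow.

**Deep-TSR** is the stroma fraction of the tumor bed, `#STR / (#STR + #TUM)`,
counted in grid cells. Cells of the other seven classes are ignored, so the
score is invariant to how much fat, mucosa or background the slide happens to
contain. Because numerator and denominator are counted on the same grid, the
overlap factor cancels and the fraction is stride-independent. Patients with
fraction at or above the 50% cutoff are stroma-high (0 points), below it
stroma-low (1 point); an exactly-50% slide goes to the high group. The
boundary rule is a package choice (the source analyses leave it unstated) and
both the cutoff and the rule are configurable.

**Deep-TIL** is the mean predicted lymphocyte-aggregate probability over the
stroma mask — an intensity of immune infiltration *within* stroma that does
not require segmenting individual lymphocytes. Grouping is by the 33rd and
66th percentiles of a reference cohort's Deep-TIL distribution (type-7 linear
interpolation between order statistics, the common default), with
lower-inclusive boundaries: score ≤ t33 → low (1 point), ≤ t66 → middle
(2 points), else high (3 points). The calibration is computed once on the
reference cohort, serialized as JSON, and applied unchanged to any other
cohort. If all reference scores coincide (t33 = t66) the calibration is
flagged degenerate and grouping collapses to low/high around the single
value, with an empty middle group.

**Deep-immune score** is the sum of the two point assignments, a four-level
composite: (high, low) → 1; (low, low) and (high, middle) → 2; (low, middle)
and (high, high) → 3; (low, high) → 4.

**Stroma-CD3 density.** On an IHC-stained slide, the stroma cells of the
patch-grid segmentation form the region of interest. A detection counts as
in-stroma iff its centroid falls inside a stroma grid cell (cell (r, c)
covers the half-open pixel block starting at ((r−1)·stride, (c−1)·stride));
the density is count / area with area = #STR · (stride · mpp)² / 10⁶ mm².
Using the *stride* footprint rather than the patch footprint keeps the area
additive under overlapping tilings. Centroid-in-cell counting (rather than
any-overlap) is deterministic and standard; both the counting rule and the
patch-level (not pixel-level) ROI are package choices where the source
workflow gives no detail. The bundled `detect_cells()` is a reference blob
detector for synthetic images only: it thresholds a brown-likeness channel
(min(R, G) − B on the unit scale, default threshold 0.3), takes 8-connected
components, and keeps those with area in [30, 5000] px². It makes no claim
about real DAB-stained tissue.

## Survival layer

Overall survival is time from surgery to death from any cause; censoring is
alive at last follow-up. The layer wraps the standard estimators: the
product-limit (Kaplan–Meier) survival curve, read as a right-continuous step
function so the 5-year rate is S(5); the k-group log-rank test with a
chi-square reference on k − 1 degrees of freedom; and Cox
proportional-hazards partial-likelihood fits with Efron tie handling (the
default in modern survival software and less biased than Breslow — the
choice is a package decision, pinned by tests). Hazard ratios are exp(coef)
with 95% Wald intervals on the log scale; categorical covariates are
dummy-coded against explicit reference levels (stage I, CEA normal,
stroma-high, TIL-low, immune score 1). Multivariate fits take the covariates
whose univariate Wald p is below 0.05, entered as whole factors. All tests
are two-sided at α = 0.05.

Discrimination is summarized two ways. Harrell's C-index is the concordance
between risk ordering and survival ordering over usable pairs, ties in risk
counting 0.5 (delegated to `survival::concordance`, verified in tests against
exhaustive pair enumeration). The integrated time-dependent AUC is computed
in-package: at each time t, cases are subjects with an observed event at or
before t, weighted by the inverse censoring survival probability 1/G(T−)
(IPCW, G estimated by Kaplan–Meier on the censoring indicator), controls are
subjects still at risk after t, and AUC(t) is the weighted probability that a
case's risk exceeds a control's (ties 0.5) — the Uno-type cumulative/dynamic
estimator. AUC(t) values computed this way agree to machine precision with an
independent reference implementation on a frozen fixture (see
`test-survival.R`). The integral over 0–5 years is the trapezoid rule over
the grid of event times in (0, 5], normalized by the grid span — i.e. a
uniform time average. Reference implementations that weight the integral by
the survival function will give slightly different *integrated* values on the
same AUC(t) curve; the choice here is the simplest one consistent with a
"trapezoid over event times" description and is pinned by tests at the AUC(t)
level, where the estimator is unambiguous. Grids longer than 250 event times
are thinned to quantiles for O(n log n) behavior at cohort scale.

## What the synthetic generator emulates

The generator exists so that every pipeline stage is testable without slides
or patient data. It emulates the *statistical structure* the analysis
assumes, with defaults pinned to the published group parameters:

- **Stroma fraction**: Normal(0.45, 0.12) clipped to [0.02, 0.98], putting
  roughly two thirds of patients below the 50% cutoff — matching the
  reported preponderance of stroma-low patients. The fraction is realized on
  the map up to one-grid-cell quantization.
- **Latent infiltration θ**: Beta with mean 0.15 and concentration 12,
  truncated below 0.5 (a stroma patch with P(LYM) ≥ 0.5 would argmax to LYM).
  θ drives both the per-cell P(LYM) in stroma (Beta with mean θ and
  concentration `dirichlet_alpha`; noise-free at α = ∞, where Deep-TIL
  recovers θ exactly) and, through the score groups, the CD3 density.
- **CD3 detections**: per patient, a density drawn Normal(μ_g, 0.1·μ_g)
  truncated at zero around the patient's immune-score group mean — defaults
  844 / 1088 / 1246 / 1708 cells/mm² — then a Poisson number of cells placed
  homogeneously in the stroma cells (the simplest model consistent with a
  density summary).
- **Survival**: exponential within score group with rate
  λ_g = −ln(S5_g)/5, so the true 5-year survival is exactly S5_g and group
  hazard ratios are analytically λ_g/λ_g′. Defaults: 58.2% and 87.4% for
  scores 1 and 4 (published); 69.2% and 77.0% for scores 2 and 3, *derived*
  from the published unadjusted hazard ratios (0.68, 0.48 vs score 1) under
  the same exponential model, since those two rates are not printed. The
  construction is self-consistent: applying it to score 4's HR of 0.27 gives
  86.4%, close to the printed 87.4%. Censoring is an administrative horizon
  (default 10 years, bracketing the cohorts' median follow-up of 5–6.5
  years) plus a 20% uniform-dropout fraction.
- **Covariates** (age, sex, stage, location, grade, CEA) are drawn
  independently of outcome except for an optional stage–score association
  knob, off by default.

The label-image route (`simulate_label_image()` → `render_rgb()` →
`mock_classifier()`) exercises the image-facing contract: stroma is grown as
patch-resolution blobs so the patch-level stroma fraction hits its target
within 0.02 by construction, lymphocyte aggregates are random disks inside
stroma with pixel coverage 0.4·θ, and the mock classifier inverts the exact
class colors to per-patch pixel fractions with optional Dirichlet(α·fractions)
noise.

What the generator does **not** emulate — and therefore what a green test
does not establish: real stain variation, scanner differences, classifier
error structure (confusions between histologically similar classes),
spatially correlated infiltration, non-exponential hazards, informative
censoring, or correlated covariates. Green recovery tests establish that the
pipeline's arithmetic is faithful to its definitions, not that the scores
carry the published prognostic signal in new patients.

## Numerical choices and degenerate inputs

- Probabilities must sum to 1 within 1e-6 per cell; classifier outputs are
  renormalized, and all-zero or wrong-arity outputs fail naming the patch.
- Map file round-trips are lossless to < 1e-9 (full-precision CSV); files
  declaring a different class order, shape, or missing metadata keys are
  rejected with specific errors.
- Slides with no stroma+tumor cells error in Deep-TSR ("no tumor-bed
  tissue"); no stroma cells error in Deep-TIL and in the density denominator;
  `score_cohort()` collects such per-patient failures in an `errors`
  attribute instead of dropping them silently.
- Percentiles use `stats::quantile` type 7; on scores 1…100 the thresholds
  are 33.67 and 66.34 (the frozen oracle in the tests).
- Cox non-convergence or separation raises an error with the underlying
  diagnostic rather than returning unstable estimates.
- Uniform censoring in `simulate_two_group_cox()` solves the censoring bound
  m from (1 − e^{−λm})/(λm) = target fraction by `uniroot`, keeping censoring
  independent of event times (dependent censoring would bias the Cox
  recovery).
- All generator randomness flows through explicit seeds; seeded code runs in
  a private RNG stream that restores the caller's `.Random.seed`.

## Limitations

- The patch classifier is a contract, not a model: no trained network ships
  with the package, and the mock classifier requires exact class colors.
- The stroma ROI is patch-level; pixel-level refinement, stain
  normalization, proprietary WSI formats, and per-cell lymphocyte detection
  on H&E are out of scope.
- The survival layer covers the validation analyses (KM, log-rank, Cox,
  C-index, iAUC); competing risks, time-varying covariates, proportionality
  diagnostics and bootstrap CIs are not implemented.
- Acceptance-style recovery targets are Monte Carlo estimates at the sample
  sizes stated in the tests; at n = 5000 the KM 5-year rate has a standard
  error near 0.5 percentage points, so rare seeds can fall outside a ±1.5
  point band without indicating a defect.
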