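---
title: "Visceral fat from projectional DXA and metabolic-syndrome cut-point diagnostics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Visceral fat from projectional DXA and metabolic-syndrome cut-point diagnostics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vatmets)
```

## The problem

Metabolic syndrome (MetS) is the clustering of abdominal obesity with raised
triglycerides, low HDL cholesterol, raised blood pressure and raised fasting
glucose. The International Diabetes Federation (IDF) definition for South
Asian adults requires a large waist circumference (WC >= 90 cm in men,
>= 80 cm in women) plus at least two of the four non-waist factors:
triglycerides >= 1.69 mmol/L, HDL < 1.04 (men) / < 1.29 (women) mmol/L,
SBP >= 130 or DBP >= 85 mmHg or antihypertensive medication, and glucose
>= 5.6 mmol/L.

Waist circumference is a crude proxy for what actually drives metabolic risk:
visceral adipose tissue. This package implements a complete, testable
pipeline around that idea:

1. estimate visceral fat mass (VFM) from a projectional DXA scan of the
   abdomen by locating the subcutaneous fat layer (SFL) boundaries;
2. compute the standard anthropometric adiposity indices and sex-specific
   anthropometric VFM prediction equations;
3. flag the IDF risk factors and the screening outcome "carries >= 2
   non-waist factors";
4. evaluate every candidate marker as a screening test (ROC/AUC with DeLong
   confidence intervals and paired comparisons, Youden and
   sensitivity-specificity-product cut-points, precision-recall curves) and
   search joint two-threshold rules that combine WC with a second marker.

Because no participant-level data ship with the package, a synthetic-data
module generates (a) abdominal *phantoms* with analytically known fat layout,
which act as ground truth for the image-analysis code, and (b) correlated
*cohorts* with realistic sex-stratified marginals, which exercise the
statistical pipeline end to end.

## The DXA abdomen model

### Scan emulation

A DXA scan is projectional: each pixel records the fat, lean and bone mass in
the tissue column behind it. The emulated scanner (`dxa_grid()`) reports any
rectangular region-of-interest mass *to the nearest gram* via `roi_mass()`,
exactly like clinical scan software; the exact per-pixel masses are kept
internally only so tests can compare against an unquantized oracle. Pixels
are 0.48 cm wide and 0.96 cm high.

The mass of a single pixel can only be recovered by inclusion-exclusion of
four quantized corner-box queries (`pixel_box_mass()`), so it carries up to
+/- 2 g of accumulated rounding error while a typical abdominal pixel holds
3-6 g of tissue. That is why the analysis never works at pixel resolution:
`strip_profile()` instead analyses strips one pixel wide spanning the *full*
ROI height, where strip masses are large enough that the 1-g resolution
contributes well under 5% relative error.

### Phantoms

`generate_phantom()` models the abdominal cross-section as an ellipse
(transverse diameter `width`, anteroposterior diameter `sagittal`) wrapped by
a subcutaneous annulus whose inner boundary is the concentric ellipse with
both semi-axes reduced by `sfl_thickness`. Each compartment is a homogeneous
fat/lean mixture (`sfl_fat_fraction`, default 0.80 by volume;
`visceral_fat_fraction`, default 0.30) with standard soft-tissue densities
(fat 0.90, lean 1.05 g/cm^3). Per-column slab areas of both ellipses have
closed forms, so every pixel mass -- and therefore the total -- is exact, and
all truth quantities (VFM, SFM, widths, boundary coordinates) are analytic.

The ellipse-plus-annulus geometry was chosen because it reproduces exactly
the quantities the image analysis extracts (abdominal width, SFL width,
sagittal diameter, annulus area) while keeping the ground truth in closed
form. The grid is aligned so the left skin edge falls on a strip junction,
the analogue of analysis boxes adjusted to follow the abdominal contour.
Phantoms contain no bone and no composition noise; see "What the synthetic
data do and do not show" below.

### Boundary detection

Working on the full-height strip profile:

* the **outer** SFL boundary on each side is the junction between the last
  zero-mass (air) strip and the first tissue strip (`detect_outer_boundaries()`),
  with resolution one strip width (0.48 cm);
* the **inner** SFL boundary is the junction between the adjacent strip pair
  with the greatest *signed* drop in percent fat mass, scanning inward up to
  the midline (`detect_inner_boundaries()`). The SFL is fat-rich and the
  viscera leaner, so the largest drop marks the transition. Ties break
  towards the outermost junction, which is conservative for SFL width. The
  drop is signed rather than absolute because an inward *rise* in %FM cannot
  be an SFL inner edge.

Two numerical guards matter in practice:

* **Mass floor.** Candidate strip pairs must each carry at least
  `min_mass_frac` (default 0.2) times the median tissue-strip mass. A nearly
  empty edge sliver has a gram-quantized %FM that can be off by several
  percentage points and would otherwise fake the maximal drop. The floor is
  ignored if it would exclude every candidate.
* **Dropout bridging.** Zero-mass strips inside the tissue span (detector
  dropout) are bridged by linear interpolation of %FM so they cannot create
  spurious junctions.

`average_cross_section()` then scales the strip masses to a representative
1-cm slice (divide by the ROI height in cm), reports the abdominal width as
the distance between the outer junctions and the SFL width as the mean of the
left and right inner-outer distances, both at junction (0.48 cm) resolution.

### From cross-section to fat masses

`compute_abdominal_fat()` reconstructs the fat compartments of the 1-cm
slice:

* **Tissue area** `A` comes from converting the slice's component masses to
  volume with the densities; under the elliptical-section model the
  DXA-measured sagittal diameter is `SD = 4A / (pi * W)`
  (`dxa_sagittal_diameter()`).
* **Sub-strip boundary refinement.** Near the projected edge of a convex
  section, the slab mass within distance `w` of the boundary grows like
  `w^(3/2)` (the chord height grows like the square root of the depth). Each
  junction-resolution boundary is therefore refined by a least-squares fit of
  that 3/2-power law to the strips around the junction -- strip masses for
  the outer boundaries, strip fat *deficits* relative to the pure-SFL
  composition for the inner ones. This matters quantitatively: the
  junction-level inner boundary is biased inward by up to half a strip, and
  the annulus area is sensitive enough to the SFL width that the raw widths
  misestimate VFM by 15-25% on phantoms, versus under 3% after refinement.
* **Subcutaneous fat mass** is the elliptical annulus area (outer ellipse
  from the refined width and the sagittal diameter, semi-axes reduced by the
  refined SFL width) times the fat volumetric density observed in the pure
  SFL strips. **Visceral fat mass** is the remaining slice fat, floored at
  zero with a warning -- a negative value diagnoses boundary failure.
* If the %FM contrast between the SFL strips and the interior is below
  `min_drop_pct` (default 5 percentage points), no subcutaneous layer is
  considered detectable and SFM is zero. A real SFL contrasts with the
  viscera by tens of points; gram quantization on light strips can fake only
  a few.
* Normalized variants divide by height squared (g/m^2) and by the slice's
  total mass (percent); `VAT_A = VFM / fat density` and `SAT_A` is the
  annulus area, reported with their ratio.

```{r phantom-example}
ph <- generate_phantom(phantom_config(width = 30, sagittal = 22,
                                      sfl_thickness = 2))
res <- analyze_dxa(ph, height = 1.70)
round(c(estimated = res$vfm, truth = ph$truth$true_vfm), 1)
```

## The synthetic cohort

`generate_cohort()` draws latent multivariate-normal scores with the
correlation matrix of `default_correlation()` and maps them to per-sex
marginals (`default_marginals()`): Gaussian for most measurements,
log-normal for triglycerides and insulin (both strongly right-skewed in
adults). Weight is derived from BMI and height, and hip circumference from
the waist:hip ratio, so the table is internally consistent; values are
rounded to realistic recording precision (0.1 cm, 0.1 kg, 1 mmHg, ...).
Measured VFM is the sex-specific anthropometric prediction plus Gaussian
noise with the published standard error of estimate (30.1 g males, 22.3 g
females), and the DXA sagittal diameter is the caliper value plus a
-0.3 +/- 2.0 cm difference, matching the reported agreement between the two
measurements. About 30% of caliper sagittal diameters are set missing,
emulating an instrument introduced mid-recruitment.

Two classes of defaults deserve comment:

* **Correlations.** Inter-variable correlations are not published for this
  population; the defaults are plausible field magnitudes (abdominal size
  measures correlate 0.5-0.85 with each other, 0.1-0.45 with metabolic
  factors, SBP with DBP at 0.7) and are documented as simulator choices, not
  estimates of any dataset.
* **Calibration of the metabolic marginals.** The headline study condition
  is that ~55% of males and ~34% of females carry >= 2 non-waist factors.
  With marginals pooled naively from published sex-stratified descriptives, a
  Gaussian copula cannot exceed ~47% in males regardless of how strongly the
  metabolic factors are correlated (positive dependence shifts probability
  mass to 0 and 4 factors at the expense of the middle, nearly cancelling in
  P(count >= 2)). The metabolic means/SDs were therefore calibrated once,
  inside the ranges spanned by the published low-risk and high-risk
  subgroups (e.g. male median TG 1.8 mmol/L, HDL mean 1.09 mmol/L, SBP mean
  123 mmHg), and frozen. At large n the defaults give 55.5% / 34.8%; the IDF
  MetS prevalence then emerges at 40% / 30% without having been targeted,
  matching the reported 40% / 29%.

### What the synthetic data do and do not show

Phantoms are noise-free, boneless, perfectly elliptical and homogeneous
within compartments; passing the recovery suite shows the geometry and
estimator logic are correct, not that the method is robust to real-scan
artefacts (bone shadows, non-convex sections, composition gradients, beam
hardening). Cohorts have Gaussian-copula dependence and exactly log-normal
skew; they validate the statistical machinery and the IDF logic, not any
population claim. In particular, AUCs and cut-points computed on synthetic
cohorts are properties of the simulator, not reproductions of any study's
cohort-specific estimates.

## Diagnostic conventions

* Positivity is `score >= cut-point`, with candidate cut-points at the unique
  observed values, so every reported operating point is achievable on the
  data. All reported cut-points follow this convention.
* AUC is the trapezoidal area, identical to the concordant-pair fraction
  with ties counted one half. Its variance (for confidence intervals and the
  paired marker comparison) uses the nonparametric placement-value (DeLong)
  estimator with a Wald interval truncated to [0, 1].
* The Youden cut-point maximizes `sens + spec - 1`; the product cut-point
  maximizes `sens * spec`. Ties (up to float tolerance) break towards the
  *lowest* threshold, which favours sensitivity in a screening context.
* Precision-recall curves use the same threshold convention; the curve is
  anchored at recall 0 with the precision of the most stringent threshold and
  integrated trapezoidally over recall *in threshold order* (sorting would
  mis-pair precisions across equal-recall plateaus).
* The joint two-threshold rule is "positive iff marker1 >= t1 AND
  marker2 >= t2" on complete cases; the grid search reports the full accuracy
  matrix (for contour plots via `autoplot()`) and the argmax pair, with ties
  broken by higher F1 and then lower thresholds. Default grid resolutions sit
  at or below each measure's recording precision (0.5 cm for WC, 1 g for fat
  mass, 0.25 kg/m^2 for BMI).
* Percentages in report tables are rounded half away from zero to integers;
  all computations keep full precision.

## Regression models

`standardized_regression()` z-scores the outcome and the fat-variable
predictors (covariates such as age and sex enter unstandardized) so that
coefficients are directly comparable effect sizes; positively skewed outcomes
(triglycerides, insulin and derived indices) are log10-transformed first.
Variance inflation factors are the diagonal of the inverse correlation matrix
of the model terms.

`fit_vfm_model()` refits the anthropometric VFM equation by forward-backward
stepwise selection on coefficient p-values. The entry/removal thresholds
(p < 0.05 in, p >= 0.10 out) are conventional defaults -- the selection
criterion is exposed as configuration precisely because "stepwise" alone does
not pin it down. Leave-one-out residuals use the exact leverage identity
`e_i / (1 - h_ii)`, PRESS is their sum of squares, and both are verified in
the tests against explicit refit-without-row-i oracles.

## Problem sizes used by the test and acceptance suites

The suites run on one CPU in a few minutes: 1000 random ROC instances (n up
to 200) against brute-force oracles, 40 joint-grid instances against a double
loop, a 44-configuration phantom geometry grid, 10 000 observations for the
binormal AUC limit, 20 000 per sex for calibration checks, and n = 5000 for
the coefficient-recovery simulation at the published noise level. These sizes
were chosen so Monte-Carlo error sits well inside each asserted tolerance.

## Known limitations

* The VFM/SFM split inherits the elliptical-annulus assumption; strongly
  non-elliptical sections bias `SAT_A` and hence VFM.
* The 3/2-power edge law is exact only asymptotically near the edge of a
  convex section; in practice it recovers phantom boundaries to a few
  hundredths of a cm, but it is a local approximation, and the refinement is
  deliberately isolated in one helper so an alternative reconstruction is a
  local change.
* Single-slice output: the pipeline quantifies the averaged 1-cm
  cross-section, not whole-abdomen VAT volume, and does not segment bone or
  vertebrae.
* The paired AUC test is asymptotic; at very small n its p-values are
  approximate (the tests compare it against a permutation oracle only up to
  Monte-Carlo tolerance).
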