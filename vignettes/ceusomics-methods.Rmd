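---
title: "Methods: ultrasomics texture analysis for CEUS liver lesions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ultrasomics texture analysis for CEUS liver lesions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Most hepatocellular carcinomas (HCC) show a characteristic contrast-enhanced
ultrasound (CEUS) pattern — arterial-phase hyper-enhancement followed by
portal/late-phase washout. A clinically important minority ("atypical" HCC,
aHCC) sustains its enhancement and thereby mimics focal nodular hyperplasia
(FNH), a benign lesion that needs no treatment. This package implements a
complete, testable pipeline for the machine-learning approach to that
differential: quantitative texture ("ultrasomics") features are extracted
from a region of interest (ROI) drawn on three images per patient — baseline
ultrasound, an arterial-phase frame and a portal-phase frame — reduced by a
filter-then-LASSO chain, and fed to an RBF-kernel SVM, alone or combined
with a radiologist's three-point confidence score. Diagnostic performance is
summarised with the standard apparatus: ROC/AUC, a Youden-optimal operating
point, sensitivity/specificity/PPV/NPV/likelihood ratios with 95% CIs,
paired DeLong and Wilcoxon comparisons, agreement statistics, and decision
curve analysis.

Because the clinical image cohort is not publicly deposited, the package
ships a first-class synthetic cohort generator that reproduces the
*statistical structure* the analysis relies on; all tests and the acceptance
suite run on it.

## The feature catalogue

Each image contributes exactly 1,044 features in five families, and each
patient 3 x 1,044 = 3,132 (phase prefixes `BL_`, `AP_`, `PP_`):

| family       | count | content |
|--------------|------:|---------|
| histogram    |    42 | 19 percentiles (P5–P95 by 5) + 23 moments/dispersion/histogram statistics of in-mask intensities |
| form factor  |    12 | area, perimeter, circularity, axis lengths, eccentricity, elongation, extent, solidity, … |
| textural     |    18 | first-order statistics of the Sobel gradient magnitude within the 1-px-eroded mask |
| GLCM         |   780 | 13 Haralick-style features x 5 distances (1–5 px) x 6 angular slots (0/45/90/135 + mean + range) x 2 grey-level settings (32, 64) |
| RLM          |   192 | 16 run-length features x 6 directional slots x 2 grey-level settings |

The exact member list of the original in-house platform is not public; the
catalogue above is this package's own composition, honouring the five named
families and the printed totals. It is configuration, not code: the count
invariant (42 + 12 + 18 + 780 + 192 = 1,044) is asserted whenever the
catalogue is built.

Numerical conventions, fixed once and used everywhere:

* **Quantization** — equal-width bins over the in-mask min–max range
  (level k covers `[min + (k-1)w, min + kw)`, maximum maps to Ng). Binning
  is ROI-relative, so all GLCM/RLM features are invariant to gain/offset
  changes — appropriate for ultrasound, where absolute intensity is not
  calibrated. A constant ROI is legal and maps to level 1.
* **GLCM** — offsets (drow, dcol): 0° = (0, d), 45° = (−d, d), 90° = (−d, 0),
  135° = (−d, −d); symmetrised, normalised to sum 1. Logs are base 2 with
  0·log 0 = 0; correlation uses the symmetric-matrix marginals and is
  defined as 1 for a degenerate (zero-variance) matrix; homogeneity is
  Σ p/(1 + (i−j)²).
* **Percentiles** — linear interpolation between order statistics
  (`stats::quantile` type 7). Moments are population moments (divide by n).
* **Perimeter** — corner-corrected chain-code estimator (0.980/axial,
  1.406/diagonal, −0.091/corner) on the traced boundary; accurate to about
  1% on digital disks, which is what makes the circularity of a rasterized
  disk land within a few percent of 1.
* **Coordinates** — 0-based, x = column, y = row, origin at the top-left
  pixel corner; a pixel is in a mask iff its centre is inside the ROI
  polygon (even-odd rule, half-open boundary convention).
* **Minimum ROI** — 16 pixels; smaller ROIs error rather than emit
  unstable texture values.

## Selection and modeling

The reduction chain runs strictly on training data, in the fixed order:

1. **Correlation filter** (|Pearson r| > 0.95 drops the lower-ranked member
   of a pair; features are visited in descending univariate-AUC order, so
   the more discriminative member survives — the tie-break is this
   package's choice, made deterministic on purpose).
2. **Univariate AUC filter** (folded AUC = max(AUC, 1−AUC) ≥ 0.6 kept,
   boundary inclusive; folding is this package's choice so "inverted"
   features are not discarded).
3. **z-normalization** by training mean and population SD; the parameters
   travel with the model and are applied unchanged to validation data.
4. **LASSO logistic regression** over a 100-value log-spaced λ path (down
   to 1e-4 · λmax), 10-fold stratified CV repeated 50 times; mean binomial
   deviance is averaged across repeats, the SE curve is the across-repeat
   mean of the CV standard errors, and the 1-SE rule picks the largest λ
   within one SE of the minimum. An events-per-variable check warns when
   events < 10 x selected covariates.

The classifier is a C-SVC with RBF kernel k(u, v) = exp(−σ‖u−v‖²), σ =
0.012 and C = 1 by default. The σ convention follows the kernlab
parameterisation (the alternative bandwidth convention is available via
`sigma_convention = "bandwidth"`). No SVM implementation is available in
the supported dependency set, so the package solves the dual with a
deterministic SMO (fixed scan order, KKT tolerance 1e-3, tightenable).
Platt probability calibration — needed for decision curves — is fitted on
out-of-fold decision values from an internal stratified CV, never on
in-sample predictions.

The experiment harness repeats (stratified 80/20 split → selection on the
training split → SVM → validation AUC) ten times from a master seed and
flags the best repeat by validation AUC (ties to the lower index). Three
predictor sets are run on shared splits: ultrasomics features, the
reader score alone (through the same SVM machinery; its ROC is invariant
to any monotone mapping of the 3-level grade, so this equals direct ROC
analysis of the score), and both combined. Paired DeLong tests use the
common validation split of the repeat where the combined model peaked;
Wilcoxon signed-rank compares the per-repeat validation AUC vectors.
Whether a published validation AUC refers to the best repeat or the
repeat average is ambiguous; both are reported.

## The synthetic cohort: what it emulates, and what it does not

`sim_config()` defaults encode the stated world: 119 FNH / 107 aHCC
patients; 128x128 images; elliptical lesions (semi-axes 18–40 px) traced
by a 36-vertex polygon with small inward radial jitter (so the mask is
strictly interior); arterial-phase hyper-enhancement in both classes with
sustained portal enhancement (FNH 90/180/160, HCC 90/170/150 on the 0–255
scale across baseline/arterial/portal — values chosen once to match the
qualitative enhancement pattern, since no image statistics are published);
additive Gaussian pixel noise (SD 4, a speckle-scale choice); and reader
grades drawn per class from (0.65, 0.20, 0.15) for FNH and (0.05, 0.10,
0.85) for HCC, giving a closed-form score-only AUC of 0.8775, near the
published radiologist AUC of 0.84. Covariates (gender, age, HBsAg,
HBV-DNA, HCV-Ab, AFP, tumor number, tumor size) are drawn from the
published per-class marginals.

Lesion texture is a Gaussian-random-field model: both classes share a
smooth long-correlation-length component (SD 4 x gap, correlation length
6 px); HCC adds a fine-grained binary bright/dark patch mixture (+/-20 x
gap, correlation length ~1.7 px). The fine patch scale matters: because
quantization is ROI-relative, a *coarse* heterogeneity model would
paradoxically give the smooth class the higher quantized GLCM contrast
(its narrow intensity range amplifies pixel noise). Placing the HCC
heterogeneity at the pixel scale makes the d = 1 co-occurrence statistics
separate in the clinically expected direction, with higher within-ROI
variance for HCC as well. `texture_contrast_gap` scales every
class-dependent component, so gap = 0 with equal enhancement means and
equal grade distributions is an exact null world.

What a green test does **not** establish: the generator has no acoustic or
speckle physics, no video/time-intensity dynamics, no anatomy, and no
reader behaviour beyond class-conditional grade sampling. Pipeline
recovery on it shows the machinery finds planted class structure at
realistic n and feature correlation — not that the published real-data
AUCs are reproducible.

All randomness flows from one master seed through documented per-patient
sub-seeds (`sub_seed(master, patient, stream)`), so partial regeneration
and end-to-end reruns are bit-identical.

## Known limitations and edge behaviour

* The univariate-AUC filter screens on the same training data that the
  LASSO cross-validates. Under a permutation null this lets a few
  selection-biased survivors through in a minority of runs (median
  selections ≤ 2, but not the near-always-empty behaviour one might
  expect). This is a property of the published filter-then-LASSO chain
  itself and is documented rather than patched.
* Degenerate inputs are first-class: constant ROIs quantize to level 1
  with correlation defined as 1; empty selection falls back to the
  reader-score model with a flag; zero-variance features are dropped with
  warnings; zero-denominator diagnostics are flagged NA, never silently 0;
  the DeLong test reports p = 1 with a degeneracy flag when the AUC
  difference has zero variance.
* TIFF input is not supported (no reader in the supported dependency set);
  PNG, single-frame little-endian DICOM (with rescale slope/intercept) and
  plain-text PGM are.
* CI methods are unstated in the source material: Clopper–Pearson exact
  intervals for proportions, stratified percentile bootstrap (B = 2000)
  for AUC and likelihood ratios. Published tables contain a few internal
  inconsistencies (e.g. an ultrasomics PPV equal to its sensitivity, and
  83/119 printing as 69.8%); only arithmetic-consistent cells are used as
  test oracles.
* Whether the original filters ran on all data or training data only is
  unstated; this package is leakage-safe by default (training only).

## Reproducing the acceptance report

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes the machine-graded catalogue counts (1,044 per image, 3,132 per
triplet) from a fresh synthetic image set; the full criteria — metric
arithmetic, texture and statistical oracles, reference-extractor agreement,
pipeline recovery, null calibration and determinism — run as
`tests/testthat/test-acceptance.R`.
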