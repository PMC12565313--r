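---
title: "Statistical and texture descriptors for breast thermogram classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical and texture descriptors for breast thermogram classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermobreast)
```

## The problem

Tumour growth recruits blood supply through angiogenesis, and the extra
perfusion raises the skin temperature over the affected breast. An infrared
camera records this as a *radiometric* image: a rectangular grid of surface
temperatures in °C (palette-coloured renderings add no quantitative
information). The analysis task is to decide, per breast, whether the thermal
pattern is consistent with an anomaly (`"A"`) or not (`"NA"`), using a
description compact enough that a clinician can see *which* quantities drive
the decision.

thermobreast implements that analysis as a chain of small, testable stages:

1. **ROI extraction** — a binary mask isolates the breast region (neck and
   axillae run warm for benign reasons); the masked region is split at the
   vertical midpoint of its bounding box into a left and a right breast
   sample, because anomalies are often unilateral and per-breast analysis is
   more sensitive than whole-image analysis.
2. **Feature extraction** — 13 descriptors per breast (below).
3. **Selection** — a per-feature Welch two-sample t-test between the A and NA
   groups; features with `p < 0.05` are retained.
4. **Classification** — linear SVM, quadratic SVM, logistic regression and a
   coarse decision tree, under stratified 5-fold cross-validation.
5. **Validation** — percentile-bootstrap confidence intervals for every
   metric and exact McNemar tests between classifier pairs.

## The descriptors

Nine first-order statistics are computed on the in-mask temperature pixels:
mean μ, population standard deviation σ and variance σ² (1/n denominator),
a Pearson-type skewness `(μ − median)/σ`, non-excess kurtosis
`E[(x−μ)⁴]/σ⁴`, min, max, the coefficient of variation `σ/μ × 100` (%), and
the energy `E = Σ T(x,y)` (the temperature sum, in °C·pixels — note this is
*not* the GLCM angular second moment, which is available separately as an
optional 14th descriptor, off by default).

Four more come from the gray-level co-occurrence matrix (GLCM). Temperatures
are quantized to `G = 256` levels, co-occurrences of neighbouring levels are
counted at distance one in the four directions 0°, 45°, 90° and 135°, the
directional matrices are integrated into one symmetric matrix, and counts are
normalized to probabilities `P(i,j)`. From `P` we take homogeneity
`Σ P(i,j)/(1+(i−j)²)`, contrast `Σ (i−j)² P(i,j)`, correlation
`Σ (i−μx)(j−μy) P(i,j)/(σx σy)`, and Shannon entropy (in bits, over the same
`G`-level in-mask histogram). Pairs with either pixel outside the mask are
skipped, so non-breast tissue never contributes texture.

Two conventions deserve emphasis because they differ from common defaults:

* **Skewness** is the Pearson-type `(mean − median)/sd`, not the standardized
  third moment; **moments use the population (1/n) denominator**. A
  sample-moment mode is available via `var = "sample"` where relevant.
* **Quantization calibration** defaults to each sample's own in-mask
  `(min, max)`. A fixed radiometric range (e.g. `calibration = c(20, 36)`)
  is available and makes gray levels comparable across samples; the default
  instead maximises within-sample contrast. This mapping is a genuine free
  parameter of the method: published studies rarely state it, and it changes
  the texture features' scale (not the selection logic).

## Feature selection

For each feature the Welch statistic

\[ t_i = \frac{\bar X_{i,1} - \bar X_{i,2}}{\sqrt{s^2_{i,1}/n_1 + s^2_{i,2}/n_2}} \]

is referred to a t distribution with Welch–Satterthwaite degrees of freedom;
two-sided `p < 0.05` retains the feature. No multiplicity correction is
applied by default — the selection threshold is a *screening* rule, not a
simultaneous inference — but Holm/BH are available via `adjust =`. Sample
(n−1) variances are used inside the statistic even though the descriptive
moments are population-form, because that is the standard Welch test;
a population-variance mode exists for exact replication of
population-moment formulations.

The package ships the per-feature p-values reported by a published analysis
of the DMR clinical thermograms (`dmr_reference_pvalues()`); applying the
rule to them retains exactly seven descriptors — homogeneity, contrast,
correlation, mean, entropy, min, max:

```{r}
apply_selection_threshold(dmr_reference_pvalues())
```

## Classifiers

* **L-SVM / Q-SVM** — support vector machines with a linear and a degree-2
  polynomial kernel (`coef0 = 1`, box constraint 1, kernel scale at the
  conventional `1/n_features` default). Features are standardized to the
  *training fold's* mean and sd.
* **LR** — plain maximum-likelihood logistic regression (threshold 0.5).
  Perfect separation on a fold is expected when the signal is strong; the
  fitted boundary is still usable, so the fitting alarms are muffled.
* **CT** — a CART tree (Gini impurity) grown permissively and post-pruned to
  at most 4 internal splits. The split cap is the defining "coarse"
  parameter: it trades training fit for generalization.

The positive class is `"A"` (anomalous), so recall is cancer sensitivity.
Cross-validation is stratified: each class is divided as evenly as possible
across folds (class counts per fold differ by at most one), and class
remainders are placed on the emptiest folds so fold *sizes* are also as even
as possible — with 265 samples split 71/194 at `k = 5`, every fold holds
exactly 53 samples with 14–15 positives. Fold assignment is deterministic
given the seed. By default folds are grouped by subject (both breasts of one
subject share a fold) to prevent within-subject leakage; `grouping =
"sample"` mirrors the fully per-breast treatment. Whether published analyses
group by subject is usually unstated, so neither mode is claimed to be "the"
original; grouping is the safer default.

## Statistical validation

**Bootstrap.** The pooled out-of-fold predictions are resampled with
replacement `B = 2000` times; each metric is recomputed per replicate and the
95% percentile interval reported. Models are *not* refit per replicate: the
interval quantifies metric variability over the observed prediction set, not
training variability. Replicates on which a metric is undefined (no positives
drawn) are skipped and counted, with a warning above 10%.

**McNemar.** For a classifier pair, `b` counts samples the first gets right
and the second wrong, `c` the reverse; the exact two-sided p-value is
`min(1, 2·P(X ≤ min(b,c)))`, `X ~ Binomial(b+c, ½)`. The exact test is valid
at the small discordance counts typical of 265 samples, where the χ²
approximation is not; its p-values are conservative and discrete by
construction, so a mid-p variant (`mode = "midp"`) is provided for
calibration studies — its null distribution is approximately uniform, while
the exact p stochastically dominates uniform. The per-fold discordance
difference `b_f − c_f` is summarised by its mean and a percentile interval
across folds; with only `k` folds this interval is descriptive, and the exact
p-value is the primary inferential output.

## The synthetic cohort generator

Clinical thermograms cannot ship with a package, so `generate_cohort()`
emulates the features of them that the pipeline consumes:

* a smooth bilateral field: baseline 28 °C plus a low-frequency lateral ramp
  (continuous random slope, span ≤ `lateral_gradient` = 1 °C) plus Gaussian
  sensor noise (`noise_sd` = 0.2 °C, matching modern microbolometer noise
  after averaging), clipped to the radiometric display range 20–36 °C;
* masks: two mirrored D-shaped half-ellipses with a midline gap, their
  semi-axes jittered ±5% *per breast* — per-breast (not per-subject) jitter
  keeps breast samples independent, which the null-calibration properties
  below rely on;
* on anomalous breasts: one radially (Gaussian) decaying hotspot of peak
  amplitude `hotspot_delta` = 2 °C at a random in-mask centre, plus
  `vessel_count` = 2 warm random-walk polylines at half that amplitude,
  dilated to ~2 px — a textural correlate of tumour-associated
  vascularization. Anomaly layers combine by elementwise maximum, so the
  in-mask peak is exactly `baseline + hotspot_delta` in the noise-free case;
* cohort structure: one case per subject, two labelled breast samples each;
  cancer subjects have one anomalous breast, or two for the
  `round(bilateral_cancer_fraction · n_cancer)` subjects drawn bilateral.
  The default composition (99 control / 42 cancer subjects) mirrors a
  public-database study cohort; with 29/42 bilateral subjects the cohort
  contains exactly 71 anomalous breasts, and subsampling the controls to 194
  reproduces that study's 265-sample per-breast composition.

Every subject is generated from a sub-seed derived from `(seed, subject
index)`, so cohorts are bit-identical under a fixed seed and stable under
subject reordering.

**What the generator does *not* model:** Pennes bioheat physics, anatomically
realistic breast shapes, camera optics/blur, and the long-tailed
inter-patient variability of real thermograms. Passing tests on synthetic
cohorts therefore demonstrate that the *pipeline machinery* is correct and
calibrated — not that the feature set attains any particular accuracy on
clinical data.

## Numerical choices and degenerate inputs

* Quantization: `level = floor((clip(T) − low)/(high − low) · G)` with
  `T = high` mapped to `G − 1`; monotone by construction.
* Constant samples: σ = 0 makes skewness/kurtosis undefined — they are
  returned as `NA` with a warning, all other fields computed; GLCM
  correlation of a constant image is reported as 1 with a warning; entropy
  is 0.
* Zero variance in both selection groups: `t = 0, p = 1` at equal means, a
  `p = 0` sentinel with a warning otherwise.
* Metrics with empty denominators are reported as 0 and flagged.
* The split column between breasts is the floor-midpoint of the mask
  bounding box, division column assigned to the right breast (half-open
  convention; which side the original studies assigned is unstated). Masks
  confined to one image half raise a "unilateral mask" error.
* Grids are indexed 1-based `(row, col)`, row 1 at top, matching raster
  order.

## Problem sizes used by the test suite

The package's properties are exercised at desk scale, chosen once: replicate-
heavy calibration studies (1000 null cohorts for the selection type-I rate,
100 seeded cohorts for selection power) run on 32×48 px grids with `G = 32`,
since test calibration is a property of the statistics, not of the image
resolution; oracle-equivalence checks run on exhaustive small grids (≤ 8×8,
`G ≤ 8`); single-run pipeline demonstrations and the acceptance script use
the full default 120×160 grids with `G = 256`. Bootstrap coverage is assessed
with `B = 1000` inside a 500-simulation outer loop.

## Known limitations

* The temperature→gray-level mapping and entropy bin count are configuration
  decisions, not reconstructions of any published study's unstated choices.
* The McNemar "difference" interval across 5 folds is descriptive only.
* Synthetic results do not transfer to clinical accuracy claims (above).
* Quality exclusions (blur, amputation) are not auto-detected; manifests may
  mark samples excluded upstream, and unilateral masks error at split time.

## A complete run

```{r, fig.width = 6, fig.height = 4}
cfg <- pipeline_config(
  cohort = cohort_config(n_control_subjects = 20, n_cancer_subjects = 10,
                         grid_height = 48, grid_width = 64, seed = 1),
  G = 64, B = 500, seed = 1
)
report <- run_pipeline(cfg)
report$cv_table
autoplot(report$selection)
```
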