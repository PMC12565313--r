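# thermobreast

Compact statistical and texture descriptors for classifying radiometric
breast thermograms.

Tumour-driven angiogenesis raises the skin temperature over an affected
breast; an infrared camera records this as a grid of surface temperatures in
°C. thermobreast turns such grids (plus binary breast masks and per-breast
labels) into a short, interpretable feature description and a benchmarked
classification, mirroring the lightweight-descriptor approach used in
thermography studies on public mastology databases:

1. **Per-breast ROI extraction** — the masked breast region is split at the
   vertical midpoint of its bounding box into left/right samples
   (`split_breasts()`), because thermal anomalies are often unilateral.
2. **13 descriptors per breast** (`extract_features()`): mean μ, population
   σ and σ², Pearson-type skewness `(μ − median)/σ`, kurtosis
   `E[(x−μ)⁴]/σ⁴`, Shannon entropy H (bits), min, max, coefficient of
   variation `σ/μ·100`, temperature-sum energy `E = Σ T(x,y)`, and the GLCM
   texture features homogeneity `Σ P(i,j)/(1+(i−j)²)`, contrast
   `Σ (i−j)² P(i,j)` and correlation `Σ (i−μx)(j−μy)P(i,j)/(σxσy)`, computed
   from a masked, direction-integrated (0°/45°/90°/135°), symmetric
   co-occurrence matrix over `G = 256` gray levels.
3. **Welch t-test selection** (`select_features()`): keep features with
   two-sided `p < 0.05` between the anomalous (A) and control (NA) groups.
4. **Four classifiers under stratified 5-fold CV** (`cross_validate()`):
   linear SVM, quadratic (degree-2 polynomial) SVM, logistic regression, and
   a coarse decision tree pruned to ≤ 4 splits.
5. **Statistical validation** (`bootstrap_ci()`, `pairwise_compare()`):
   B = 2000 percentile-bootstrap CIs for every metric and exact McNemar
   tests for every classifier pair.

A synthetic cohort generator (`generate_cohort()`) emulates bilateral
temperature fields with tumour-like hotspots and vessel structures, so the
whole pipeline runs and is tested without clinical images. Real radiometric
data in the same manifest/grid/mask format feeds the identical code path
(`read_cohort()`).

## Worked example

```r
library(thermobreast)

cfg <- pipeline_config(
  cohort = cohort_config(n_control_subjects = 20, n_cancer_subjects = 10,
                         grid_height = 48, grid_width = 64, seed = 1),
  G = 64, B = 500, seed = 1
)
report <- run_pipeline(cfg)
report
#> <thermo_report> seed 1, config 936a69ba
#> selected features: mean, std, variance, skewness, kurtosis, entropy, max, cv, homogeneity, contrast, correlation
#> # A tibble: 4 x 6
#>   classifier accuracy          precision         recall        specificity f1
#> 1 lsvm       100.00% +/- 0.000 100.00% +/- 0.000 100.00% +/- ... ...
#> 2 qsvm       100.00% +/- 0.000 ...
#> 3 lr         100.00% +/- 0.000 ...
#> 4 ct         100.00% +/- 0.000 ...

dplyr::select(tidy(report$selection), feature, statistic, p_value, selected)
#> # A tibble: 13 x 4
#>    feature     statistic  p_value selected
#>  1 mean            5.26  1.63e- 4 TRUE
#>  2 std            39.6   5.14e-12 TRUE
#>  ...
#>  7 min            -0.650 5.28e- 1 FALSE
#> 10 energy          0.283 7.81e- 1 FALSE
#>  ...
```

What the numbers mean: with the default synthetic conditions (2 °C hotspots
against 0.2 °C sensor noise) anomalous breasts are cleanly separable, so the
Welch screen retains the location/texture features that the generator
actually perturbs (the per-breast `min` and the mask-area-dominated `energy`
carry no signal and are dropped), and all four classifiers reach 100%
cross-validated accuracy with zero discordant McNemar pairs. Shrink
`hotspot_delta` or raise `noise_sd` to study degradation; set
`hotspot_delta = 0` for null cohorts, on which selection holds its 5%
type-I rate and classifiers fall back to the majority rate.

The package also ships the per-feature p-values reported by a published
DMR-cohort analysis; the selection rule applied to them keeps exactly the
seven descriptors homogeneity, contrast, correlation, mean, entropy, min,
max:

```r
apply_selection_threshold(dmr_reference_pvalues())
```

Plotting: `autoplot(report$selection)` (p-value lollipop),
`autoplot(report$runs[[1]])` (per-fold metrics), and `plot_thermogram()`
for the temperature grids themselves. `tidy()`/`glance()` methods cover the
selection, CV, bootstrap and McNemar result types.

A thin CLI wrapper is installed under `exec/`:

```sh
thermobreast simulate --config cohort.yaml --out dir --seed 7
thermobreast run      --config run.yaml    --out dir --seed 7
```

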