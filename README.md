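# lbptex

Rotation-invariant texture analysis of brain MR volumes for dementia
classification research.

Structural MR images of people with Alzheimer's disease (AD), Lewy body
dementia (LBD) and normal controls (NC) differ not only in volumetry but in
the local texture of white matter (WM) and white-matter lesions (WML).
`lbptex` implements the full analysis chain needed to test that signal:

1. **Texture operators** — for each voxel of a masked region, on 2D slices,
   the local binary pattern (LBP) over `P` circular samples at radius `R`:

   `LBP_{P,R} = Σ_p s(g_p − g_c) · 2^p`, with `s(x) = 1` if `x ≥ 0`, else 0,

   made rotation invariant either by minimizing over circular bit rotations
   (`ri`) or by mapping uniform patterns (at most 2 bit transitions) to
   their 1-bit count and the rest to a miscellaneous label `P + 1`
   (`riu2`); plus the rotation-invariant local contrast
   `VAR_{P,R} = (1/P) Σ_p (g_p − μ)²`, the population variance of the
   neighbour gray values. Fractional sample positions are bilinearly
   interpolated.
2. **WML segmentation** — slice-wise thresholding of a FLAIR-like volume at
   `scale_factor ×` the mode of the slice's brain-intensity histogram.
3. **Features** — for each of three neighbourhood geometries
   (P=8/R=1, P=12/R=2, P=16/R=4), the pooled ROI-wise LBP and contrast
   value distributions are reduced to 8 statistics each (mean, SD,
   variance, median, IQR, entropy, skewness, kurtosis): 48 features per
   subject.
4. **Class rebalancing** — SMOTE oversampling of minority classes up to the
   majority-class size (by default inside each training partition only).
5. **Evaluation** — stratified nested 10-fold cross-validation: best-first
   forward wrapper feature selection (macro F-measure under inner 10-fold
   CV, stale after 5 non-improving expansions) around a 10-tree random
   forest; total accuracy and per-class precision/recall reported as
   mean (SD) over the outer folds.
6. **Synthetic cohorts** — MRI-like phantoms (ellipsoidal brain, WM
   subregion, Gaussian-random-field texture whose in-plane correlation
   length is the class signal, optional hyperintense lesions) so every
   stage can be exercised and calibrated without clinical data.

## Worked example

Simulate a two-class cohort whose classes differ only in texture
correlation length (1 vs 4 voxels), extract the 48 texture features per
subject inside the WM mask, and evaluate the classifier with nested CV:

```r
library(lbptex)
library(dplyr)

spec <- cohort_profile("signal-2class", seed = 7, volume_shape = c(32, 32, 6))
spec$classes$A$n <- 12; spec$classes$B$n <- 12

cohort <- simulate_cohort_features(spec)
cohort[1:4, 1:6]
#> # A tibble: 4 × 6
#>   subject_id label LBP_P8_R1_mean LBP_P8_R1_sd LBP_P8_R1_variance
#> 1 sub-001    A               35.9         54.0              2911.
#> 2 sub-002    A               37.9         57.3              3286.
#> 3 sub-003    A               36.4         53.7              2881.
#> 4 sub-004    A               39.6         57.7              3331.

fit <- run_nested_cv(select(cohort, -subject_id),
                     nested_cv_config(outer_folds = 5, inner_folds = 5, seed = 7))
fit
#> <nested_cv> 5 outer folds, 2 classes (A, B), SMOTE: within-folds
#>   accuracy           1.00 (0.00)
#>   precision_A        1.00 (0.00)
#>   precision_B        1.00 (0.00)
#>   recall_A           1.00 (0.00)
#>   recall_B           1.00 (0.00)
fit$selected[[1]]
#> [1] "LBP_P8_R1_mean"
```

Each summary row is the mean over outer folds with the sample SD in
brackets: the texture classes here are cleanly separable, the wrapper
selects a single LBP feature, and every held-out subject is classified
correctly. `tidy(fit)` returns the per-fold metric values, `glance(fit)`
the summary tibble, and `autoplot(fit)` a per-fold dot plot. Real volumes
enter through `read_volume()` / `read_mask()` and `run_pipeline()`; a thin
command-line wrapper with `simulate` / `segment` / `extract` / `classify` /
`run-all` subcommands is installed at `inst/cli/lbptex`.

## Documentation

The methods vignette (`vignettes/lbp-texture-pipeline.Rmd`) describes the
operators, the model assumptions, every tunable parameter, the numerical
conventions and the known limitations in detail.
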