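---
title: "Rotation-invariant LBP texture analysis for brain MRI classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rotation-invariant LBP texture analysis for brain MRI classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lbptex)
```

## The problem

Dementias with different aetiologies — Alzheimer's disease (AD), Lewy body
dementia (LBD) — and healthy ageing leave different microstructural traces
in cerebral white matter. Those traces are visible to *texture* operators
even where lesion volumes do not differ between groups. This package
implements a complete, testable pipeline for that analysis: per-voxel
rotation-invariant local binary patterns (LBP) and local contrast inside a
white-matter (WM) or white-matter-lesion (WML) region of interest,
48 distribution-summary features per subject, SMOTE class rebalancing, and
nested cross-validated wrapper feature selection around a small random
forest.

## The texture operators

For a centre voxel with gray value $g_c$, the operator samples $P$ points
equally spaced on a circle of radius $R$ pixels within the 2D slice,
anticlockwise from the pixel directly to the right; sample $p$ sits at
$(-R\sin(2\pi p/P),\, R\cos(2\pi p/P))$ in (row, column) offsets. Values
at fractional positions are bilinearly interpolated from the four
surrounding pixels; offsets within $10^{-9}$ of an integer are snapped, so
the axis-aligned samples of the $P=8, R=1$ geometry are exact pixel reads.

The basic code thresholds each neighbour against the centre,

$$\mathrm{LBP}_{P,R} = \sum_{p=0}^{P-1} s(g_p - g_c)\,2^p,\qquad
  s(x) = \begin{cases}1 & x \ge 0\\ 0 & x < 0,\end{cases}$$

so ties ($g_p = g_c$) contribute a 1. The weight is $2^p$ — the binomial
weighting by bit position that makes the code unique. Two
rotation-invariant variants are provided:

* **ri** — the minimum of the code over all $P$ circular bit rotations,
  one identifier per rotation class;
* **riu2** — patterns whose *uniformity* $U$ (the number of circular 0/1
  transitions, wrap-around pair included) is at most 2 are labelled by
  their count of 1-bits, giving exactly $P+1$ uniform labels; all other
  patterns collapse to the miscellaneous label $P+1$.

On the transition count there are two conventions in circulation: the
circular count (the formula above; `lbp_uniformity(bits)`) and a
linear-scan count that omits the wrap-around pair
(`lbp_uniformity(bits, circular = FALSE)`), under which the pattern
`00000011` has $U = 1$ rather than 2. The operators use the circular
convention — it is the one that yields exactly $P+1$ uniform rotation
classes — and the linear reading is kept available because worked examples
quoted for this measure sometimes follow it.

Because LBP discards magnitudes it is invariant to gray-scale shifts; it
is complemented by the rotation-invariant local contrast

$$\mathrm{VAR}_{P,R} = \frac1P \sum_{p=0}^{P-1}(g_p-\mu)^2,\qquad
  \mu = \frac1P\sum_p g_p,$$

the *population* variance (divisor $P$) of the neighbour values, which is
shift-invariant but deliberately not scale-invariant.

**Invariance under monotone intensity transforms.** Sign thresholding
depends only on the ordering of gray values, so LBP codes are unchanged by
any strictly increasing intensity transform *at integer sample positions*.
Where samples are bilinearly interpolated, a nonlinear monotone transform
does not commute with the interpolation, and codes at interpolated
positions can differ; positive affine transforms always commute. The test
suite checks the exact property where it holds exactly (affine transforms
for interpolated geometries; arbitrary monotone transforms for the
all-integer $P=4, R=1$ geometry). The interpolation itself is evaluated in
difference form, so a locally constant patch interpolates to exactly its
own value and the tie rule stays deterministic.

`compute_texture_maps()` applies the operators to every masked voxel whose
sampling disc lies inside its slice (slices taken along `slice_axis`,
default the third axis — the axial convention for conventionally oriented
volumes). Neighbour values are read from the full slice, not just the
mask, so ROI-edge texture sees its true surroundings. Masked voxels whose
disc would leave the slice are *skipped*, not padded — padding would
fabricate texture — and counted in `n_skipped`.

## WML segmentation

`segment_wml()` segments hyperintensities from a FLAIR-like volume slice
by slice: brain voxels whose intensity strictly exceeds
`scale_factor` × (mode of the slice's brain-intensity histogram) are
labelled lesion. The mode is the centre of the fullest bin of a fixed-bin
histogram (default 256 bins) spanning the slice's intensity range, ties
broken toward the lower bin; slices with fewer than
`min_brain_voxels_per_slice` (default 50) brain voxels yield no estimate
and no lesions. The scale factor is acquisition-dependent and has **no
default** — calibrate it on data with known lesions or on synthetic
volumes (`generate_volume()` records a ground-truth lesion mask; a factor
near 1.4 recovers contrast-2 lesions with Dice ≥ 0.9 in the test suite).
Because the threshold scales with the mode, the segmentation is invariant
to positive rescaling of the volume and shrinks monotonically as the scale
factor grows. Whether the original procedure used ≥ or >, and mode over
brain-only versus all nonzero voxels, is not documented; this
implementation uses strict > over brain-masked voxels and documents rather
than claims that choice. Manually edited masks can be supplied to
`run_pipeline()` in place of the automatic result.

## The 48 features

For each of three neighbourhood geometries — $P=8, R=1$; $P=12, R=2$;
$P=16, R=4$ — the per-voxel LBP codes and contrast values are pooled over
all slices of the ROI into one distribution each, and each distribution is
reduced to 8 statistics: mean, SD (divisor $n-1$), variance, median, IQR
(linear-interpolation quantiles), Shannon entropy in bits, skewness and
excess kurtosis (adjusted Fisher–Pearson, e1071 type 2). That yields
2 descriptors × 3 geometries × 8 statistics = 48 named features in a fixed
order (`feature_names()`).

Conventions the summary relies on:

* "variation" is interpreted as the **variance** (SD²), not the
  coefficient of variation, which is undefined for zero-mean data;
* LBP codes are summarized directly as numeric values even though the
  labels are nominal — deliberately faithful to summarizing the code
  image itself; histogram-bin features are out of scope;
* entropy of discrete codes uses the empirical label distribution; for
  continuous contrast values a 32-bin histogram over [min, max] (bin
  count chosen once; the value distribution, not the bin count, carries
  the class signal);
* a constant sample is degenerate: entropy, skewness and kurtosis are
  defined as 0; fewer than 8 values in an ROI is an error, since the
  higher moments are meaningless below that;
* pooling across slices (rather than averaging per-slice statistics) is
  assumed; permuting slice order provably leaves the features unchanged.

## Class imbalance

Cohorts are imbalanced (the motivating design has 57 AD, 16 LBD and 36
control subjects). `smote_balance()` raises every class to the
majority-class count: each synthetic row is $x + u\,(x_{nn} - x)$ with $x$
a minority row, $x_{nn}$ one of its $k = 5$ nearest same-class neighbours
(Euclidean distance on the native feature scale — the pipeline deliberately
performs no normalization), and $u$ a single uniform(0,1) draw per row, so
every synthetic subject lies on a segment between two real ones.
Where SMOTE enters the cross-validation matters: applying it before
splitting leaks interpolated copies of test subjects into training folds.
The default is therefore `within-folds` — SMOTE inside each outer training
partition only — with `pre-split` available for comparability with
protocols that balanced first, and `off` to disable it.

## Nested cross-validation and wrapper selection

`run_nested_cv()` estimates generalization with stratified 10-fold outer
CV. Within each outer training set (after optional SMOTE), best-first
forward selection searches feature subsets from the empty set, expanding
the best open subset by single-feature additions; each candidate subset is
scored by the mean macro F-measure of a 10-tree random forest under inner
stratified 10-fold CV, with subset scores cached so nothing is evaluated
twice. The search stops after 5 consecutive expansions that fail to improve
the best subset (and immediately once the score reaches its upper bound of
1, after which no strict improvement is possible). The forest is Breiman's
random forest as implemented in the randomForest package (bagged trees,
$\sqrt d$ features per split) — established code, not re-derived; the
selection loop, CV scheme and metrics are implemented here. The f-measure
is macro-averaged F1 (per-class harmonic mean of precision and recall,
classes averaged, undefined classes contributing 0), the natural reading
for a 3-class problem. The inner procedure is a plain stratified 10-fold
CV; a bootstrap-resampling inner loop is a described alternative that the
explicit parameter set (10 folds) overrides.

Per outer fold the selected-feature forest predicts the untouched test
fold; the confusion matrix (rows actual, columns predicted) gives total
accuracy $T$ = trace/total, per-class precision $P_k$ (column-wise) and
recall $R_k$ (row-wise). A class never predicted in a fold has undefined
precision; such values are excluded from fold averaging by default
(`undefined_as_zero = TRUE` scores them 0 instead, matching reports that
print 0.00 for never-predicted classes). Metrics are summarized as
mean and sample SD (divisor $n-1$) over folds — the "m(s)" format.
If selection returns the empty set (possible when no subset beats the
majority-vote baseline), the fold's model falls back to all features.
Determinism: a single configuration seed fixes folds, SMOTE draws and
forest fits; identical runs are bit-identical.

Stratified folds deal each class's members round-robin, handing remainder
instances to the currently least-loaded folds, so fold sizes differ by at
most one and per-class counts by at most one.

## The synthetic cohort generator

`generate_volume()` builds an ellipsoidal brain mask (semi-axes one voxel
inside the half-dimensions) with a concentric WM-like ellipsoid at 0.62 of
those semi-axes, and fills the brain with a class mean plus a Gaussian
random field: white noise smoothed in-plane with a Gaussian kernel of SD
equal to the class's correlation length ℓ (truncated at 3 SD, border
renormalized), then rescaled so the marginal SD over brain voxels equals
σ. Smoothing is in-plane because the texture operators are 2D and
slice-wise; ℓ directly modulates what they measure — smoother fields
produce fewer non-uniform binary patterns — which makes correlation length
an honest, mechanistically understood class signal. Optional spherical
lesions (count, radius range, contrast ratio > 1) are set to
contrast × mean plus the local field and recorded in a ground-truth mask
nested inside WM.

Default study conditions (`cohort_profile()`): class mean 100, σ = 10,
volumes 48 × 48 × 8 voxels — large enough that all three neighbourhood
geometries map thousands of WM voxels per subject while a full calibration
run stays cheap. The `paper-imbalance` profile reproduces the 57/16/36
AD/LBD/NC imbalance with ℓ = 2/4/1; `balanced` uses 30 per class;
`null` gives three classes identical parameters (ℓ = 2, 30 per class, the
same size as the balanced design so the null calibration is read at the
same n); `signal-2class` has two classes of 30 with ℓ = 1 versus 4 — a
four-fold correlation-length difference.

What the generator does *not* emulate: anatomy, bias fields, scanner
noise spectra, multi-site effects, partial-volume edges. Passing the
calibration suites therefore shows the pipeline detects controlled
stationary-texture differences at realistic sample sizes and is honest at
the null — not that clinical accuracy on real cohorts is reproduced.

## Calibration results computed by the test suite

Two end-to-end checks anchor the pipeline (seeds fixed in the tests):
a null cohort (identical class parameters) must land inside the 95%
binomial chance band around 1/3 accuracy, and the `signal-2class` cohort
must reach mean nested-CV accuracy ≥ 0.9. Both run at the default
48 × 48 × 8 volume size with 30 subjects per class. The brute-force oracle
suite re-derives every texture-map value on random slices from a literal
per-pixel implementation kept independent of the package internals.

## Numerical choices and degenerate inputs

* Ties $g_p = g_c$ threshold to 1, exactly per the step function.
* Offsets are snapped to integers within $10^{-9}$ before interpolation.
* Raw codes are exact for $P \le 30$ (integer-valued doubles); the ri
  lookup table is built per $P$ and cached.
* Histogram-mode ties break toward the lower bin; a constant slice's mode
  is the constant itself.
* An all-constant feature matrix cannot grow a tree; the ensemble
  degenerates to a majority-class predictor rather than stalling.
* Volumes and masks must share a voxel grid; mismatches are errors, never
  resampled away. Mask values outside {0, 1} are coerced to 1 with a
  warning.

## Known limitations

* 2D slice-wise analysis only; 3D spherical neighbourhoods are future
  work.
* Code-valued summaries treat nominal labels as numbers; that is the
  faithful design here, but histogram-based LBP features are the common
  alternative elsewhere.
* The wrapper search is greedy best-first; it returns a good subset, not
  the optimum, and its cost grows with the number of features.
* Contrast features are not scale-invariant and the pipeline performs no
  intensity normalization; cross-scanner intensity scaling will move
  them.
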