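---
title: "Standardizing brain MR intensities for radiomics: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Standardizing brain MR intensities for radiomics: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radiomr)
```

## The problem

MR intensities carry no absolute physical meaning: the same brain imaged on
two scanners (or with two protocols) produces histograms that differ by
gain, offset, smooth spatial bias and noise.  Radiomic features — summary
statistics and texture descriptors extracted from a tumour region of
interest (ROI) — inherit that variability, which breaks test–retest
reproducibility and degrades any classifier trained on multi-scanner
cohorts.  `radiomr` implements a complete, testable pipeline for studying
this problem: intensity normalization, grey-level discretization, feature
extraction, paired-acquisition robustness statistics and a tumour-grade
classification harness, exercised end-to-end on synthetic paired-scanner
brain phantoms.

The pipeline assumes its inputs are already bias-corrected, resampled to a
1 mm isotropic grid, skull-stripped and co-registered; those are standard
external pre-processing steps and are outside this package's scope.  The
synthetic-data module produces inputs directly in that state.

## Intensity normalization

Three methods are implemented, all statistics computed over the brain mask
only (tumour voxels included — the tumour occupies a small fraction of the
brain, so no tumour exclusion is applied) while the transform is applied to
every voxel:

* **Z-Score**: $I'(x) = (I(x) - \mu_{brain}) / \sigma_{brain}$.
* **WhiteStripe**: $I'(x) = (I(x) - \mu_{ws}) / \sigma_{ws}$, where
  $\mu_{ws}, \sigma_{ws}$ are the mean and standard deviation of the
  "white stripe": the voxels within ±5% (on the intensity axis) of the
  normal-appearing white-matter (NAWM) intensity mode.
* **Nyul**: piecewise-linear histogram matching.  A standard histogram is
  learned by averaging landmark percentiles
  $C_L = [1, 10, 20, \dots, 90, 99]$ across a training set (each image's
  $[p_1, p_{99}]$ interval affinely mapped onto a standard scale, default
  $(0, 100)$); a new image is transformed by the piecewise-linear map that
  sends its own landmarks onto the standard ones, with the end segments'
  slopes extended beyond the outer landmarks.

Standard deviations use the population (divide by $N$) convention
throughout; the scale factor is irrelevant downstream but must be fixed for
exact tests.

### Numerical choices

**White-stripe estimation.**  The NAWM mode is found from a histogram of
brain voxels with a Freedman–Diaconis bin width (clamped to 16–2048 bins),
Gaussian-smoothed (sd 2 bins).  Local maxima with smoothed height at least
10% of the global maximum are candidate modes; for a T1-like contrast the
*last* (highest-intensity) prominent mode is selected, for a T2-like
contrast the largest.  Both the prominence threshold and the mode rule are
arguments.  The ±5% band is interpreted on the intensity axis
($[0.95\mu, 1.05\mu]$ for a positive mode); a proportional band degenerates
when the mode sits near zero (e.g. on an already-normalized image), so the
half-width is never allowed below one histogram bin, and a non-positive
mode falls back to a symmetric absolute band.  Because the mode is only
bin-centre accurate, re-running WhiteStripe on its own output is
near-identity but not exact — an intrinsic property of the intensity-band
reading of the ±5% rule.

**Nyul landmarks are exact order statistics.**  Landmark percentiles are
computed as the inverse empirical CDF value $x_{(\lceil np/100 \rceil)}$
rather than an interpolated quantile.  The reason is a contract we consider
part of the method: after transforming, the image's recomputed landmark
percentiles must reproduce the standard landmarks *exactly*.  With
interpolated quantiles the landmark is a synthetic value lying strictly
between two order statistics, the piecewise map has a kink there, and the
recomputed quantile of the output (which interpolates across that kink)
misses the standard landmark by up to $\sim 10^{-4}$ relative on
desk-scale volumes.  With order-statistic landmarks the map's node sits on
an attained intensity and the recomputation is exact to the last bit.
First-order percentile features (P10, P90, median, IQR) instead keep the
interpolated (R type 7) convention common in radiomics software; the two
conventions serve different purposes and are documented where used.

## Grey-level discretization

Two schemes cluster ROI intensities into integer levels before texture
matrices are built:

* **FBS** (fixed bin size, absolute):
  $X_d = \lfloor X / w_b \rfloor - \lfloor X_{min} / w_b \rfloor + 1$.
* **FBN** (fixed bin number, relative):
  $X_d = \lfloor N_g (X - X_{min}) / (X_{max} - X_{min}) \rfloor + 1$,
  with the maximum assigned $N_g$.

FBN is invariant under any positive affine intensity map, which is the
mechanism by which relative discretization makes texture features immune to
affine scanner effects — and hence why no-normalization, Z-Score and
WhiteStripe give *identical* texture features under FBN.  To make FBS
comparable across differently scaled conditions, the bin width is derived
from a nominal bin count via $w_b = \mathrm{mean\ range} / N_{bins}$, where
the mean ROI intensity range is computed over the whole cohort of one
(sequence × normalization) condition and reused for every case in it.
Computing it per normalization condition is required for nominal bin counts
to be comparable across conditions; the package computes it after
normalization for the same reason.  The supported nominal bin grid is
8–1024 in powers of two, with 32 the conventional default.

Floating-point boundary ties are guarded: a relative epsilon
($10^{-12}$-scale) is added before each `floor`, so levels are reproducible
across platforms when a value lands a rounding error below a bin edge.
First-order Entropy and Uniformity reuse the experiment's active
discretization; the other 16 first-order statistics use raw intensities.

## Features

Each ROI yields 91 features: 18 first-order statistics and 73 texture
features over five matrix families (GLCM 22, GLRLM 16, GLSZM 16, NGTDM 5,
GLDM 14), with IBSI-style definitions.  Matrices are 3D at Chebyshev
distance 1: GLCM and GLRLM are built per direction over the 13 unique 3D
directions and their features averaged across directions (GLCM symmetric);
GLSZM zones are 26-connected components of equal level; NGTDM uses the
26-neighbourhood mean of in-mask neighbours (voxels with no in-mask
neighbour are excluded); GLDM counts, for each voxel, the 26-neighbours
within `alpha = 0` levels of the centre, and stores dependence $d$ in
column $d + 1$ so the matrix index stays positive in the feature formulas.

Degenerate inputs never produce non-finite features: correlation-type GLCM
features of a zero-variance matrix return their limiting value (1 for
Correlation, 0 for Imc1), entropies of a single-cell matrix return 0,
constant-ROI skewness and kurtosis return 0, and NGTDM Coarseness with a
zero denominator returns the sentinel $10^6$.  Kurtosis is the non-excess
(Pearson) form.  The GLCM set is the 22 "active" features of the
pyradiomics-era convention — the documented 24 minus SumAverage (redundant
with JointAverage by symmetry) and MCC.

Every matrix builder is tested against an independent brute-force
enumeration (triple loops over voxels) on dozens of random ≤6³ fixtures
with exact count equality.

## Robustness statistics

For a cohort scanned twice, per-feature agreement across the two
acquisitions is quantified by:

* **ICC(2,1)** — two-way random-effects, absolute-agreement,
  single-measurement intra-class correlation from the standard ANOVA mean
  squares.  This is the conventional test–retest form; absolute agreement
  (unlike consistency forms) penalizes systematic offsets.  A table with
  zero total variance returns 1 by convention.
* **CCC** — Lin's concordance,
  $2 s_{xy} / (s_x^2 + s_y^2 + (\mu_x - \mu_y)^2)$, population moments.

A feature is **robust** iff both statistics are strictly greater than the
threshold (default 0.8).  Histogram similarity within a pair is measured by
the Jensen–Shannon divergence with base-2 logarithm (range $[0, 1]$) on 256
equal-width bins spanning the union of the two brain-mask intensity ranges
— a shared support is required and the bin count is a documented choice.

## Classification harness

The two-grade task is evaluated with five classifier families at fixed,
seeded default configurations (recorded by `classifier_defaults()`):
logistic regression (`glm`), Gaussian naive Bayes (`e1071::naiveBayes`),
RBF SVM (`e1071::svm`, cost 1, probability outputs), random forest
(`randomForest`, 500 trees) and a multi-layer perceptron (`nnet`, 8 hidden
units, decay 0.01, 200 iterations).  Cross-validation is stratified 5-fold;
within each fold, feature columns are standardized using training-row
statistics only and applied unchanged to the held-out rows, so test rows
never influence any fitted parameter.  Per fold and family, balanced
accuracy (mean of per-class recall, probability threshold 0.5) and ROC-AUC
(Mann–Whitney formulation, ties ½) are recorded; the 25 pooled
(fold × family) scores are summarized by their mean and a 1000-iteration
bootstrap percentile interval.  Pooling the 25 scores as the bootstrap
resampling unit is a design choice: the alternative (resampling folds or
families separately) conditions on one grouping and was not adopted.

Feature-set models: 1 = first-order only, 2 = texture only, 3 = both,
4 = the robust subset from a paired-cohort robustness report (a condition
whose robust set is empty is skipped with a recorded warning).

Conditions are compared by factorial ANOVA (main effects, type-II sums of
squares, so the unbalanced grade design is handled) followed by Tukey HSD
for factors significant at 0.05.  Type II was chosen over type I/III
because the grid is unbalanced only through skipped conditions and no
interaction term is fitted.

## The synthetic-data generator

The generator emulates the two study designs the analysis needs:

* **Paired cohort** (default 20 subjects): one anatomy per subject, two
  acquisitions with independently drawn scanner effects, identical brain
  and tumour masks across the pair.
* **Graded cohort** (default 108 low-grade + 135 high-grade): one
  acquisition per case, scanner effects drawn from heterogeneous
  (multi-site) ranges.

Each anatomy is an ellipsoidal brain (default 64³ voxels at 1 mm — the
smallest grid where texture matrices and white-matter mode detection are
meaningful at desk-scale runtimes) with three tissue compartments in the
T1-like order CSF < GM < WM (means 40/80/120, WM the largest compartment so
its histogram mode is detectable), and a spherical-ish tumour placed inside
the brain whose volume fraction is drawn from a truncated normal with mean
7.5% and sd 3.7% of the brain.  Tumour texture is a stationary correlated
Gaussian field: the grade effect sizes are the field standard deviation
(8 low vs 14 high, with ±~17% per-case jitter) and its correlation length
(3.0 vs 1.6 voxels), plus a tumour mean shift (140 vs 150, per-case jitter
sd 4).  These give second-order features true signal and first-order
features a moderate one; the magnitudes were fixed once as plausible
desk-scale effect sizes.

The scanner model is
$a \cdot I^{\gamma} \cdot b(x) + b_0 + \varepsilon$: a smooth multiplicative
bias field (sum of low-order separable polynomials, renormalized to mean 1
over the brain), an intensity exponent, gain, offset and additive Gaussian
noise.  With $\gamma = 1$ and no bias the map is exactly affine — the
regime in which FBN texture features are provably invariant.  The default
paired-cohort effect is affine: gain uniform in [0.6, 1.8], offset in
[−20, 20], noise sd 2.4 (2% of the WM mean).  The magnitude of real
1.5 T-vs-3 T intensity differences is not a quantity the package can claim;
the ranges are free configuration parameters chosen to span a clearly
visible scanner effect.

In the graded cohort the `confound_gain` knob (default +0.2 on low-grade
gains over a [0.5, 1.5] base range, offsets in [−30, 30]) correlates
scanner gain with grade *against* the intrinsic tumour-intensity signal:
high-grade tumours are intrinsically brighter but tend to be scanned with
lower gain, so the grade signal in raw intensities is masked and intensity
normalization genuinely matters for classification.  Every generator is a
pure function of its (config, seed) arguments; per-case seeds are spawned
from the master seed by fixed arithmetic and recorded in each case and
manifest.

**What the phantoms are not.**  No atlas-based anatomy, no k-space or
Rician noise physics, no multi-sequence co-registration errors, no partial
volume modelling.  Passing tests on these phantoms demonstrates that the
pipeline's mathematics and plumbing behave as specified (exact
normalization contracts, FBN invariance, robustness ordering, calibrated
harness) — not that any particular robustness count or accuracy would be
observed on clinical data.

## Problem sizes and reproducibility

The shipped experiments run at desk scale by choice: 64³ voxel grids, 20
paired subjects, 243 graded cases, a single-bin (32) grid slice for the
acceptance checks, 50 label-permutation repetitions and 2000 null ANOVA
simulations.  All tables are written with fixed formatting and no
timestamps, so re-running `run_experiment()` with the same configuration
reproduces every CSV/JSON byte for byte; outputs carry the verbatim
configuration, a deterministic fingerprint and all seeds.

## Known limitations

* The white-stripe ±5% band in intensity units is one of two defensible
  readings (the other being a quantile band); the intensity reading was
  chosen and is only bin-centre accurate near degenerate modes.
* The identity of the four features that deviate from IBSI definitions in
  the extraction software this package parallels is not public; all 91
  features here follow IBSI-style formulas.
* Tumour voxels are included in the brain statistics during normalization
  (deliberately, matching the small-tumour assumption); for very large
  lesions this biases $\mu_{brain}$ and the Nyul landmarks.
* The five classifiers use fixed default configurations; no hyperparameter
  search is performed, by design.
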