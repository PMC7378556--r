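# radiomr

Brain-MR intensities are arbitrary: the same anatomy scanned on two
machines differs by gain, offset, smooth bias and noise, and radiomic
features extracted from a tumour ROI inherit all of it.  `radiomr` is an R
package for studying — and fixing — that problem.  It implements, as one
tested pipeline:

* **Intensity normalization**: Z-Score
  (`(I − μ_brain)/σ_brain`), WhiteStripe (`(I − μ_ws)/σ_ws` with automated
  estimation of the normal-appearing white-matter mode and its ±5% stripe),
  and Nyul piecewise-linear histogram matching with the landmark
  configuration `C_L = [1, 10, 20, …, 90, 99]`.
* **Grey-level discretization**: absolute (fixed bin size,
  `X_d = ⌊X/w_b⌋ − ⌊X_min/w_b⌋ + 1`) and relative (fixed bin number,
  `X_d = ⌊N_g (X − X_min)/(X_max − X_min)⌋ + 1`), with the cross-condition
  scaling rule `w_b = mean_range / N_bins` and the 8–1024 bin grid.
* **Features**: 18 first-order statistics and 73 texture features over
  GLCM (22), GLRLM (16), GLSZM (16), NGTDM (5) and GLDM (14), 3D at
  distance 1 with 13-direction averaging, IBSI-style definitions.
* **Test–retest robustness**: Jensen–Shannon divergence between paired
  intensity histograms (base 2), ICC(2,1), Lin's CCC, and the dual rule
  *robust ⇔ ICC > 0.8 and CCC > 0.8*.
* **Classification harness**: five classifier families (logistic
  regression, naive Bayes, SVM, random forest, MLP), stratified 5-fold CV
  with fold-internal feature standardization, balanced accuracy and
  ROC-AUC, 1000-iteration bootstrap CIs, factorial type-II ANOVA with
  Tukey HSD, and feature-set models 1–4 (first-order / texture / both /
  robust-only).
* **Synthetic cohorts**: paired two-scanner and two-grade brain phantoms
  (ellipsoidal brain, three tissue compartments, correlated-field tumour
  texture, configurable scanner effects) so the whole design runs
  end-to-end without patient data.

It is aimed at radiomics methodologists who need a reproducible harness
for pre-processing decisions rather than a clinical tool.

## Worked example

Generate a 10-subject paired cohort whose two acquisitions differ by an
affine scanner effect plus noise, then ask which first-order features
survive, with and without Z-Score normalization:

```r
library(radiomr)
cfg  <- cohort_config(n_paired = 10, seed = 2026)
ecfg <- experiment_config(cohort = cfg, methods = c("none", "zscore"),
                          modes = "FBS", bins = 32, seed = 2026)
rob <- run_robustness_experiment(ecfg, which = "firstorder")
rob$robust_counts
#>   method mode bins      class n_robust n_total
#> 1   none  FBS   32 firstorder        2      18
#> 2 zscore  FBS   32 firstorder       16      18
round(tapply(rob$jsd$jsd, rob$jsd$method, mean), 4)
#>   none zscore
#> 0.4849 0.0026
```

Without normalization only 2 of the 18 first-order features are robust
(the affine-invariant shape statistics, skewness and kurtosis); after
Z-Score normalization 16 of 18 are, and the mean Jensen–Shannon divergence
between the paired brain histograms collapses from 0.48 to 0.003.  The
per-feature statistics are in the report:

```r
head(rob$reports[["zscore/FBS/32"]]$features[, c("feature", "icc", "ccc", "robust")], 4)
#>                  feature       icc       ccc robust
#> 1      firstorder.Energy 0.9998676 0.9998529   TRUE
#> 2 firstorder.TotalEnergy 0.9998676 0.9998529   TRUE
#> 3     firstorder.Entropy 0.9255251 0.9179293   TRUE
#> 4     firstorder.Minimum 0.9338061 0.9269882   TRUE
```

`run_classification_experiment()` evaluates the grade-classification grid
(normalization × discretization × bins × feature-set model) the same way,
and `run_experiment()` runs both stages and writes a byte-reproducible
artifact tree (CSV/JSON with the verbatim config, fingerprint and seeds).

A thin command-line front end ships at `inst/cli/radiomr.R` with
subcommands `simulate`, `normalize`, `discretize`, `extract`,
`robustness`, `classify` and `run-all`, e.g.

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/radiomr.R", package="radiomr"))')" \
  simulate --config cohort.json --out cohort/ --cohort graded
```

## Package layout

* `R/phantom.R` — synthetic cohorts and scanner effects
* `R/normalize.R` — Z-Score, WhiteStripe, Nyul
* `R/discretize.R` — FBS/FBN and the bin-width scaling rule
* `R/firstorder.R`, `R/texture-matrices.R`, `R/texture-features.R` — the
  91 features
* `R/robustness.R` — JSD, ICC(2,1), CCC, robustness reports
* `R/classify.R`, `R/anova.R` — the evaluation harness
* `R/experiment.R`, `R/cli.R` — orchestration and the CLI

The methods vignette (`vignettes/radiomr-methods.Rmd`) documents the
models, conventions, numerical guards and the limits of what the synthetic
phantoms can show.
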