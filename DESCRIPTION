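Package: radiomr
Title: Intensity Standardization and Radiomic Feature Robustness for Brain MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for standardizing brain MR images before
    radiomic analysis.  Implements three intensity-normalization methods
    (Z-Score, WhiteStripe with automated white-stripe estimation, and Nyul
    piecewise-linear histogram matching), absolute (fixed bin size) and
    relative (fixed bin number) grey-level discretization, extraction of 18
    first-order and 73 textural features (GLCM, GLRLM, GLSZM, NGTDM, GLDM),
    paired-acquisition robustness statistics (Jensen-Shannon divergence,
    ICC(2,1), Lin's concordance correlation) and a tumour-grade
    classification harness with five classifier families, stratified
    cross-validation, bootstrap confidence intervals and factorial
    ANOVA/Tukey comparisons.  A synthetic-data module generates paired
    two-scanner and two-grade brain phantom cohorts so the whole design can
    be exercised end-to-end without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    igraph,
    RNifti,
    randomForest,
    e1071,
    nnet,
    car
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
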