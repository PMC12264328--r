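Package: radstab
Title: Radiomic Feature Stability Under Segmentation Uncertainty
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify how segmentation uncertainty affects the
    reproducibility and scan-rescan repeatability of radiomic features.
    From a stack of stochastic segmentation replicates the package computes
    mean predictions, aleatoric/epistemic/predictive uncertainty maps and
    confidence-level masks; extracts a pinned roster of 105 IBSI-style
    radiomic features (first-order, 3-D shape, GLCM, GLRLM, GLSZM, GLDM,
    NGTDM) slice-wise with averaging; classifies feature stability with
    two-way intraclass correlation coefficients (consistency and absolute
    agreement); selects the optimal confidence threshold; and runs a
    group-discrimination analysis with bootstrapped mRMR feature selection,
    leave-one-patient-out logistic regression and DeLong ROC comparison.
    A synthetic cohort generator with controllable boundary uncertainty and
    calibration makes the whole pipeline testable without imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    pROC,
    RNifti,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
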