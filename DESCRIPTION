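Package: codenoise
Title: Pattern Uncertainty and Controls-Based Denoising for Image-Derived
    Read-Out Patterns
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies the sampling uncertainty of group-difference
    read-out patterns from image-derived subject-by-voxel data (squared
    standard error SE2 and the normalized noise component estimator NCe),
    and implements controls-based denoising (CODE): removal of
    nonpathological-variance (NPV) patterns learned by PCA from an
    independent control sample, with a weighted variant whose denoising
    weight is optimized by minimizing the predicted pattern-expression
    error. Provides the noise/signal reduction estimators (NRe, SRe), the
    net benefit estimator (NBe) that predicts whether denoising will help
    before it is applied, leave-one-pair-out evaluation with ROC/AUC,
    Youden cut-points and DeLong AUC comparison, a synthetic-cohort
    simulator under the linear pathology model, and NIfTI/CSV ingestion
    and serialization utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    RNifti,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
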