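Package: gleasonomics
Title: Multiomics Machine Learning for Whole-Mount Gleason Grade Risk Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested, reusable pipeline for predicting whole-mount Gleason
    grade risk group (ISUP >= 3 versus < 3) from multiomics data in prostate
    cancer. Implements variant-pathogenicity metascoring with gene- and
    pathway-level genetic disruption, tumor mutational burden and copy-number
    burden; PET standardized-uptake-value metrics and an IBSI-convention
    first-order/GLCM radiomics subset; immunohistochemistry H-scores with
    per-marker aggregation; a leakage-free 100-fold stratified Monte Carlo
    cross-validation engine with fold-wise k-nearest-neighbor imputation,
    z-scoring, minimum-redundancy-maximum-relevance feature selection,
    random-search tuning of five classifier families and isotonic
    calibration; explainability via permutation importance, Monte Carlo
    Shapley values and surrogate decision trees; and a synthetic multiomics
    cohort generator with planted, configurable label effects for end-to-end
    validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    class,
    e1071,
    fgsea,
    glmnet,
    IRanges,
    jsonlite,
    ranger,
    RNifti,
    rpart,
    xgboost
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
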