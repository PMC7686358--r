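Package: rpradiomics
Title: Radiomic Prediction of Radiation Pneumonitis After Lung SBRT
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end radiomic analysis pipeline for predicting grade >= 2
    radiation pneumonitis (RP) from pretreatment planning CT of lung
    stereotactic body radiation therapy (SBRT) patients. Builds
    dose-threshold lung regions of interest (LV0/LV5/LV10/LV20), computes a
    486-feature radiomic vector per region (histogram, GLCM, GLRLM, GLSZM
    and NGTDM texture features on the original volume and on eight
    single-level 3-D wavelet subbands), derives dose-volume histogram
    parameters (V5, V10, V20, mean lung dose), selects
    selection-frequency signatures by repeated LASSO logistic regression,
    and fits balanced-subset ensemble-averaging classifiers evaluated by
    ROC analysis. Includes a seeded synthetic cohort generator with a
    planted texture effect so the whole pipeline is testable without
    patient data.
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
    Rcpp,
    rlang,
    RNifti,
    stats,
    tibble,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
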