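Package: habicat
Title: Habitat Radiomics Pipeline for Tumor Grading on Synthetic CT Phantoms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Habitat radiomics analysis for pathological grading of lung
    tumors: isotropic resampling and peritumoral expansion of tumor masks,
    voxel-wise first-order entropy maps, K-means clustering of intensity and
    entropy super-voxels into intratumoral habitats, extraction of an
    851-feature radiomic signature (shape, first-order, texture, and wavelet
    classes), reference-batch empirical-Bayes ComBat harmonization, a
    two-step logistic-regression classifier architecture with SMOTE, mRMR
    and LASSO feature selection, and evaluation with DeLong AUC inference,
    balanced accuracy and linear SHAP attributions. Includes a synthetic
    3-D phantom generator with planted ground truth so the whole pipeline
    is testable end to end without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    RNifti,
    glmnet,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    sva,
    yaml
Config/testthat/edition: 3
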