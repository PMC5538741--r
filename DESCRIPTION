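Package: cpinjury
Title: Automated Quantification of Brain Injury Aetiologies from Structural MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies three aetiologies of brain injury seen in children with
    cerebral palsy from structural MRI: cortical shape abnormality (thickness,
    curvature and sulcal depth z-scores against a normative cohort), white and
    grey matter lesion burden (EM/MRF tissue segmentation with explicit lesion
    outlier classes, reported as regional volumes in mL), and localized
    ventricular enlargement (a PCA statistical shape model of healthy lateral
    ventricles with enlargement attributed to adjacent deep grey matter).
    Injury biomarkers are related to clinical scores through negativity
    constrained LASSO models with unpenalized covariates, post-selection OLS
    refits, held-out test-set validation and nested-model ANOVA. A synthetic
    3D brain phantom generator with known ground truth (tissue labels, lesions,
    ventricle enlargement, cortical thinning, bias field, Rician noise) makes
    the whole pipeline testable end to end without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    RNifti,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    glmnet,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
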