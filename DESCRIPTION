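Package: spectRadiomics
Title: Standardized Radiomics of Myocardial Perfusion SPECT for Coronary
    Calcium Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for standardized 3D radiomics analysis of myocardial
    perfusion stress SPECT volumes. Implements a 487-descriptor feature
    catalog with fixed-bin-number discretization and from-scratch 3D texture
    matrices (GLCM, GLRLM, GLSZM, GLDZM, NGTDM, NGLDM), a blind-to-outcome
    feature-selection cascade, Spearman univariate screening with
    Benjamini-Hochberg control, and stepwise linear regression with AIC under
    a nested resampling protocol combined across repetitions by Fisher's
    method, to relate perfusion-image texture to per-artery coronary artery
    calcification scores. Includes a synthetic SPECT cohort generator
    (left-ventricle shell geometry, vascular segment masks, clinical
    covariates and hurdle-model calcium scores) so the whole pipeline is
    testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    RNifti,
    jsonlite,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
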