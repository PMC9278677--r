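Package: vmatqa
Title: Patient-Specific VMAT QA Prediction from MLC Kinematics and
    Fluence Texture
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Predicts per-arc gamma passing rates (GPR) for
    volumetric-modulated arc therapy (VMAT) patient-specific quality
    assurance from plan complexity features.  Reads VMAT plans from
    DICOM-RT Plan files or a portable JSON exchange format, extracts
    multileaf-collimator (MLC) leaf-speed and leaf-acceleration
    features and gray-level co-occurrence matrix (GLCM) texture
    features of the reconstructed fluence map, filters out-of-control
    historical GPR records with an individuals control chart, labels
    arcs PASS/FAIL against an institutional warning level, and fits
    AdaBoost classification and bagged regression-tree models with
    sensitivity, specificity, RMSE and feature-importance reporting.
    Includes a seeded synthetic-cohort generator so the whole pipeline
    is testable without clinical data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    rpart,
    randomForest,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
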