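Package: panelfs
Title: SVM-Embedded Forward Selection of Blood Biomarker Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovery and validation of small diagnostic biomarker panels from
    protein-microarray-style expression cohorts. Implements floor-and-log2
    preprocessing with robust-regression age/gender correction, two greedy
    forward feature-selection algorithms embedded in a radial-kernel support
    vector machine scored by leave-one-out cross-validation (SVMFS and SVMTFS),
    a repeated stratified-split evaluation battery (sensitivity, specificity,
    PPV, NPV, FDR, FOR, accuracy, AUC), cross-cohort validation, per-group
    LOOCV, two-threshold "banded" interval classifiers for single markers, and
    a synthetic cohort generator that plants banded, correlated and confounded
    markers for end-to-end testing.
License: MIT
Encoding: UTF-8
Imports:
    e1071,
    MASS,
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
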