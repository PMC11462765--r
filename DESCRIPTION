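Package: echomontage
Title: ECG-Gated Echocardiogram Montages and Convolutional Screening for
    Cancer Therapy-Related Cardiomyopathy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building deep-learning-ready inputs from parasternal
    short-axis echocardiogram cine loops and for screening childhood cancer
    survivors for treatment-related cardiomyopathy. Extracts ECG-gated still
    frames at fractional R-R landmarks, removes burned-in annotations by
    temporal-variance sector masking, assembles standardized 2x2 grayscale
    montages (single-cycle and two-cycle formats), applies case/non-case
    labeling and anthracycline dose-equivalence rules, trains a compact
    two-block convolutional network under patient-level cross-validation,
    and compares input formats with the combined 5x2-fold cross-validation
    F-test. A synthetic ultrasound phantom generator (contracting short-axis
    ventricle with speckle, burned-in overlays, and a synchronized ECG)
    makes every stage testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    png,
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    withr,
    yaml
Config/testthat/edition: 3
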