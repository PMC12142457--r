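Package: brachysel
Title: Applicator Selection Decision Support for Cervical HDR Brachytherapy
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Decision support for choosing between interstitial (Syed) and
    intracavitary (tandem & ovoids) applicators in high-dose-rate
    brachytherapy of locally advanced cervical cancer. Encodes contoured
    anatomy (clinical target volumes, organs at risk and the digitized
    central tandem) into a 3-channel voxel volume of label codes and
    tandem-axis distance maps, classifies it with a compact six-block 3D
    convolutional network trained with a binary cross-entropy plus L1 loss
    under class-balanced patient-level sampling and rigid augmentation, and
    benchmarks against twenty handcrafted geometric features fed to an
    ANOVA-F-ranked, SMOTE-balanced soft-voting ensemble of four classical
    classifiers. Includes a synthetic pelvic-anatomy generator with an
    analytic geometric ground-truth rule for end-to-end validation without
    patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    e1071,
    randomForest,
    rpart,
    class
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    RNifti,
    optparse
Config/testthat/edition: 3
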