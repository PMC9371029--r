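Package: cropsift
Title: Crop-Type Mapping from Historical Label Rasters with Cross-Year
    Ensemble Sample Filtering
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for producing per-pixel crop-type maps from monthly
    satellite image time series when the only training labels available are
    imperfect historical crop-data-layer (CDL-style) rasters. Implements
    monthly median compositing with cloud filtering, gap interpolation and
    Savitzky-Golay smoothing of per-pixel series; spatiotemporal training
    sample selection (5x5 homogeneity and rotation-parity stability rules);
    cleaning of candidate samples by cross-year classifier consistency
    voting (leave-one-year-out unanimity for training years, all-model
    voting for the test year); training and grid search for SVM, decision
    tree, random forest and a fixed-topology multilayer perceptron;
    kappa/overall/producer/user accuracy statistics; per-pixel mapping; and
    a dual-length time-series correction for wetland-as-rice confusion. A
    seeded synthetic scene generator with known crop rotation, phenology,
    cloud gaps and label noise makes every stage testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    jsonlite,
    ranger,
    rpart,
    signal,
    stats,
    tiff,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
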