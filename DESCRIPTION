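Package: rgbpheno
Title: RGB Image-Based Phenotyping for Single-Plant Field Trials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating dry matter yield and selection classes of
    individual plants in spaced field trials from aerial RGB imagery. The
    package clips orthoimages into per-plant plots, extracts a 542-entry
    descriptor (HSV colour histogram, Hu invariant moments, Haralick texture
    statistics, two green-pixel counters and four visible-band vegetation
    indices), and fits three model framings: regression of dry matter yield,
    binary selection of the top-yielding fraction, and prediction of an
    ordinal breeder's score aggregated to three classes. Random-forest models
    built on bagged CART trees support the full hyperparameter grid (split
    criterion, depth, cost-complexity pruning, class weights) with
    mean-decrease-in-impurity feature selection, and a compact convolutional
    network provides a transfer-learning style training harness. A seeded
    synthetic field-image generator with known ground truth supports
    validation of the entire pipeline, including a breeder's-score benchmark
    linear model with tunable predictive power.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    jsonlite,
    png,
    rpart,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    ranger,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
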