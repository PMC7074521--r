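Package: seedvision
Title: Computer-Vision Classification of Chickpea Varieties from Color and
    Texture Features
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: A machine-vision pipeline for discriminating visually similar
    chickpea (Cicer arietinum L.) varieties from images of seed bunches on a
    dark background. Provides HSI-rule threshold segmentation with
    small-object removal, extraction of 48 color-space statistics and 80
    gray-level co-occurrence matrix (GLCM) texture features per image,
    cultural-algorithm wrapper feature selection, multilayer perceptrons
    whose architectures are tuned by particle swarm, ant colony, and harmony
    search metaheuristics, a majority-voting ensemble, confusion-matrix and
    ROC/precision-recall evaluation, and a seeded synthetic image generator
    emulating the imaging setup so the whole pipeline is testable without a
    physical seed collection.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    jsonlite,
    generics,
    png,
    stats,
    grDevices,
    utils,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    pROC,
    yaml,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
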