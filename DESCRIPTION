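Package: gwokelm
Title: Genetic-Seeded Grey Wolf Optimization for Kernel Extreme Learning Machines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for wrapper feature selection and hyperparameter tuning of
    kernel extreme learning machine (KELM) classifiers with a grey wolf
    optimizer whose initial population is seeded by a short genetic-algorithm
    run (G-GWO). Includes the closed-form KELM fit and predict routines,
    canonical grey wolf and genetic-algorithm operators, a subset-size
    penalized fitness for feature selection, an encoder-decoder segmentation
    hyperparameter encoding with a smoothed mean-Jaccard objective and a
    deterministic desk-scale surrogate evaluator, a fundus-image
    preprocessing and augmentation pipeline (bilinear resize, median filter,
    CLAHE, a 30-variant augmentation catalogue with sevenfold expansion),
    confusion-matrix performance metrics, and synthetic data generators so
    the whole pipeline is exercisable without external datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    jsonlite,
    png,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
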