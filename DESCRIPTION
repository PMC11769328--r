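Package: hsiseed
Title: Bench-Top Hyperspectral Imaging Pipeline for Seed Protein Phenotyping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for estimating seed protein content from bench-top VNIR/SWIR
    hyperspectral scans. Implements ENVI cube input/output, radiometric
    calibration from dark and white-reference scans, fiducial-marker
    co-registration of the two sensor frames by RANSAC homography, rule-based
    seed segmentation with morphological cleanup and grid labeling, per-seed
    spectral and band-ratio feature engineering with random-forest and
    support-vector regression, and a hybrid 3D/2D convolutional network with
    optional global-attention and squeeze-and-excitation blocks for protein
    regression and 3-class protein classification. A synthetic scene simulator
    generates VNIR/SWIR scene pairs with known geometry, calibration frames and
    protein-dependent seed reflectance so the full pipeline can be exercised
    and validated without proprietary scanner data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    signal,
    randomForest,
    e1071,
    igraph,
    jsonlite,
    png,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
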