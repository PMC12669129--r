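Package: phenostage
Title: Instance-Level Growth-Stage Classification of Rosette Plants from
    Top-View Multi-Plant Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A detection-ordering-regression-staging pipeline for
    phenotype-based growth staging of basil-like rosette plants grown in
    fixed multi-pot beds and imaged from above. Provides a procedural
    synthetic-scene generator with exact ground truth (boxes, leaf-pair
    labels, anomaly tags), a pluggable plant-detector contract with a
    classical colour-based reference detector and a full detection
    evaluation suite (IoU, precision/recall, F1-confidence curves, mAP),
    bounding-box post-processing (confidence filtering, nested-box
    removal, exact-count frame skipping, K-means row ordering), dataset
    construction utilities (instance cropping, manifests, frame
    exclusion, ratio splits), a small convolutional leaf-pair regressor
    trained with the Huber loss and AdamW, BBCH-style leaf-pair to
    growth-level mapping, and the evaluation metrics and k-fold
    cross-validation used to assess the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    grDevices,
    jsonlite,
    png,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
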