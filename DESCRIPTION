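Package: mciic
Title: Majority Clustering for Imbalanced Image Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Preprocessing and training pipeline for binary image
    classification under severe class imbalance. The majority class is
    partitioned into Nc clusters by k-means on extracted image features,
    with Nc chosen by an elbow criterion on the within-cluster sum of
    squared errors; the binary task is then trained as an (Nc+1)-class
    problem, optionally with class-weighted augmentation or a
    class-weighted cross-entropy loss, and predictions are folded back
    to binary for minority-class precision, recall and F1 reporting.
    Includes a synthetic generator of imbalanced image sets with planted
    majority modes, a deterministic fallback feature extractor, an
    experiment harness comparing six weighting/clustering configurations,
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    png,
    jsonlite,
    yaml,
    withr,
    optparse
Suggests:
    testthat (>= 3.0.0),
    mclust,
    cluster,
    EBImage
Config/testthat/edition: 3
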