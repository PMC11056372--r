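Package: dermoscan
Title: Automated Dermoscopic Skin Lesion Analysis and Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end analysis of dermoscopic skin-lesion images: DullRazor-style
    hair removal and a median/Gaussian/Lee smoothing chain, lesion segmentation by an
    adaptive snake (active contour) and by seeded region growing, texture description
    through 20 gray-level co-occurrence matrix (GLCM) statistics, ABCD-rule shape and
    colour descriptors (asymmetry index, border irregularity, colour variance,
    area, equivalent diameter, roundness), and benign/malignant classification with a
    feed-forward neural network and a kernel SVM. Includes a seeded synthetic
    dermoscopy-image generator with exact ground-truth masks, the full
    confusion-matrix metric suite (accuracy, sensitivity, specificity, precision,
    F1/Dice, Jaccard, Matthews correlation), and a reconstruction oracle that recovers
    integer confusion matrices from printed percentage metrics.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    png,
    nnet,
    e1071,
    tibble,
    dplyr,
    tidyr,
    generics,
    ggplot2,
    jsonlite,
    stats,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
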