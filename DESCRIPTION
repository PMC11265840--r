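Package: pyramidHER2
Title: Pyramid Sampling and Confidence-Based Aggregation for HER2
    Scoring of IHC Tissue Cores
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Multi-scale patch-set construction ("pyramid sampling") from
    immunohistochemically stained breast tissue-core images, class-weighted
    training of a pluggable four-class HER2 classifier, and a replicate /
    top-k-confidence / maximum-score inference protocol, together with
    Monte Carlo analysis of the inference hyperparameters, tissue-microarray
    core detection by circular Hough transform, a multi-rater consensus
    labeling protocol, and the associated evaluation battery (confusion
    matrices, per-class specificity, adjacent-pair accuracy, grouped
    ROC/AUC).  A synthetic IHC-like image generator with a class-conditional
    membrane-staining model makes the whole pipeline exercisable end-to-end
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    png,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse,
    tiff,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
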