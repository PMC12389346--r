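Package: budpredict
Title: Beyond-Use-Date Prediction for Compounded Oral Solid Dosage Forms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimates beyond-use dates (BUDs) of compounded oral solid
    preparations from molecular descriptors, excipient composition, packaging
    and storage conditions. Implements a descriptor categorization framework
    with composite molecule, molecular-structure and storage classes, a
    27-feature encoder, tree-ensemble BUD regression with a seven-family model
    comparison, a six-metric evaluation report and descriptor correlation
    screen, formulation-grid batch prediction with BUD-range histograms, and a
    synthetic-data generator with known ground truth for parameter-recovery
    checks. Ships a curated 53-record stability dataset covering 22 active
    pharmaceutical ingredients and six excipients.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    randomForest,
    ranger,
    readr,
    rlang,
    rpart,
    stats,
    tibble,
    utils,
    xgboost,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
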