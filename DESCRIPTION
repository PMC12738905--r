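Package: graftlight
Title: Light-Recipe Design and Closed-Loop Control for Grafting-Ready
    Tomato Seedlings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for cultivating tomato seedlings that meet the
    morphological requirements of automatic grafting machines. Provides
    multi-criteria grafting-suitability scoring of seedling indicators with
    game-theoretically combined subjective (AHP) and objective (entropy)
    weights; a synthetic plant-twin growth simulator encoding the known
    qualitative light responses of tomato seedlings; forward prediction of
    hypocotyl length and stem diameter from light recipes with
    gradient-boosted and classical regressors, including time-series
    partitioning, training-set augmentation and Gaussian-process
    hyperparameter search; two-stage differential-evolution inverse design
    of light recipes; and a rule-based daily closed-loop controller that
    adjusts the recipe when measured morphology deviates from prediction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    kernlab,
    lhs,
    purrr,
    ranger,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    xgboost,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
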