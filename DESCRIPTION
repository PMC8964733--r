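Package: maxrange
Title: Automated Maximum-Entropy Range Estimation Within Native Regions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An automated workflow for estimating species ranges from
    presence-only occurrence records on a regular latitude/longitude grid.
    Occurrence tables are filtered into three data types (raw records,
    presence cells, spatially thinned cells), maximum-entropy niche models
    with L1-regularized linear/quadratic/product/hinge/threshold features
    are fitted against the full native-region background, candidate models
    across feature-class combinations and regularization multipliers are
    calibrated by jackknife or spatial block cross-validation and selected
    by AICc with a testing-AUC fallback, and predictions are evaluated with
    ROC and precision-recall metrics against presence-background data or
    reference ranges. A seeded synthetic-world generator provides
    environmental stacks, native-region masks, occurrences drawn from known
    niches and expert-style reference ranges so the full pipeline can be
    exercised and validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    geosphere,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
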