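Package: matchexplain
Title: Population- and Individual-Level Explainers for Propensity Score
    Matching
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Diagnoses which subjects a propensity-score-matched analysis
    actually covers. Estimates propensity scores (logistic regression,
    classification tree, or bagged trees, with a plug-in for externally
    computed scores), performs greedy K:1 nearest-neighbor caliper matching
    with or without replacement, labels every subject as matched ("in") or
    unmatched ("out"), and then explains inclusion at the population level
    with a cross-validation-pruned classification tree and at the individual
    level with local surrogate (LIME-style) linear models. Includes a
    synthetic registry-cohort generator with presets emulating published
    hospital-registry marginals so the whole pipeline is testable without
    restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    rpart,
    optparse
Config/testthat/edition: 3
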