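Package: injurycast
Title: Injury-Risk Decision Models for GPS-Derived Football Training Load
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for modelling non-contact injury risk in professional
    football from wearable-GPS external-load data. Aggregates session-level
    records into player-microcycle feature tables (training-week and
    match-day splits, one-to-three microcycle lags, player motor profiles,
    acute:chronic workload ratios and related derived load ratios) and runs
    three decision systems over them: a banded expert-rule scorer, a Mamdani
    fuzzy rule-based system with centroid defuzzification, and a
    gradient-boosted tree baseline with SMOTE rebalancing, median imputation
    and repeated stratified cross-validation. Includes a synthetic squad
    generator with a configurable logistic injury hazard so the full
    pipeline can be exercised and tested without access to club data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
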