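Package: nutricost
Title: Activity-Based Costing of Multisectoral Nutrition Programmes
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements the full costing pipeline for multisectoral
    agriculture-nutrition programmes using the activity-based-costing
    ingredients (ABC-I) approach: coding of line-item expenditure ledgers to
    standardized activity/input/stage categories, allocation of personnel and
    shared costs, economic-cost valuation (capital annuitization, tax rules,
    opportunity cost of frontline-worker overtime and beneficiary time),
    cost-cube aggregation with unit costs by treatment arm and beneficiary
    denominator, and a gamma-distribution Monte Carlo probabilistic
    sensitivity analysis with tornado ranking. Ships a calibrated synthetic
    data generator so every stage is testable without institutional data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
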