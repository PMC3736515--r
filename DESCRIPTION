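Package: npmagree
Title: Agreement Between Nutrient Profile Models for Regulating Food
    Advertising to Children
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A declarative engine for nutrient profile models (NPMs) of the
    kind proposed to regulate broadcast food advertising to children:
    category-matched threshold criteria and FSA/Ofcom-style points scoring,
    together with the dataset-assembly steps used to build advertised-food
    datasets (exclusion rules, brand representatives, meal nutrient
    averaging, generic-table supplementation) and the agreement statistics
    used to compare models (commercial-weighted approval proportions with
    food-based binomial confidence intervals, pairwise Cohen's kappa with
    banded interpretation, food-guide category breakdowns, and per-food
    approving-model counts). A seeded synthetic-data generator emulates the
    statistical structure of a UK 2008 advertised-food dataset so the whole
    pipeline is testable without proprietary data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    e1071,
    optparse
Config/testthat/edition: 3
Collate:
    'utils.R'
    'nutrients.R'
    'food.R'
    'assembly.R'
    'model.R'
    'engine.R'
    'agreement.R'
    'synthetic.R'
    'pipeline.R'
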