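Package: regforge
Title: Turning Patient-Centered Registry Data into Research-Ready Datasets
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A systematic framework for converting clinically collected,
    patient-centered registry data into research-ready datasets, exercised
    on a collaborative-care depression registry data model. Provides a
    declarative data-quality rule engine organised around five rule
    families (attribute domain constraints, relational integrity,
    historical data rules, state-dependent object rules, and attribute
    dependency rules), missing-data handling including recovery of missing
    care-episode start dates from contact logs, classification of episodes
    into enrolled, opt-out and not-approached cohorts, index-date and
    observation/outcome-window construction for cross-sectional studies,
    subgroup summary tables and data-flow-diagram emission, and a synthetic
    registry generator with planted ground truth and error injection so
    every pipeline stage is testable without access to protected health
    information.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
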