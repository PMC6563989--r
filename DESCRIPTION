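Package: fimd
Title: Weighted Questionnaire Scoring and Comparison of Animal Disease Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to validate, score, compare and report on animal-model
    validation sheets built on an eight-domain weighted questionnaire
    (the Framework to Identify Models of Disease, FIMD). Implements the
    same-weight scoring system (100 points split equally over eight
    validation domains and then over the questions within each domain),
    exclusion-adjusted equivalent scores, uncertainty and similarity
    factors, validation levels from definite-answer percentages, radar
    plots of per-domain ratios, and grouped aggregation of per-study
    reporting-quality (ARRIVE-adapted) and risk-of-bias (SYRCLE-adapted)
    checklists. Sheets are read and written as YAML or JSON, study
    assessments as CSV, and a seeded synthetic generator produces
    complete fixtures for every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    yaml,
    jsonlite,
    tibble,
    ggplot2,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
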