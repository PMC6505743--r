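Package: mewsaudit
Title: Modified Early Warning Score Pipelines for Protocol-Adherence Audits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to audit track-and-trigger early-warning-score practice on
    a surgical high-dependency unit. Implements the Modified Early Warning
    Score (MEWS) band table as a configurable scoring engine, groups
    asynchronous time-stamped vital-sign recordings into bedside assessments
    with a 15-minute window rule, audits whether each follow-up assessment
    met the response-protocol interval dictated by the current score, and
    compares study arms (completeness, per-element missingness, adherence,
    time-to-next-assessment strata) with rank-sum and 2x2 contingency tests.
    A synthetic two-arm cohort generator with known ground truth (per-element
    missingness, protocol compliance, automated-device usage, deterioration
    episodes) makes every pipeline stage testable without patient data.
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
    tools,
    tidyr,
    utils,
    yaml
Suggests:
    ggplot2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
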