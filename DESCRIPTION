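Package: audcohort
Title: Hearing-Aid Outcome Cohorts from Electronic Health Records
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for building audiological outcome cohorts from
    relational electronic-health-record extracts: merging multi-station
    demographic records, cleaning raw audiometric entries and computing
    four-frequency pure-tone averages, detecting hearing-care events from
    code lists, assigning a hearing-aid fitting-date proxy from battery
    orders, estimating long-term hearing-aid use persistence and the
    medication possession ratio from battery-order (refill) histories,
    scoring IOI-HA self-report surveys, and deriving a Chronic Condition
    Indicator multimorbidity index from ICD-9 diagnosis streams. Includes
    a synthetic cohort generator with known ground truth for validation,
    and an end-to-end pipeline producing descriptive and stratified
    outcome summaries.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
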