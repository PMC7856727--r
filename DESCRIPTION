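Package: hkpim
Title: Hong Kong-Specific Potentially Inappropriate Medication Criteria
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building, validating and applying an explicit
    potentially inappropriate medication (PIM) assessment list for older
    adults, modelled on the Hong Kong-specific criteria. Implements the
    reference-criteria candidate selection rule, a two-round modified
    Delphi consensus engine based on Likert median and interquartile-range
    thresholds, a machine-readable 164-statement ATC-coded criteria set,
    hierarchical ATC prefix matching, a patient-level screening engine
    with cohort prevalence summaries, and seeded synthetic-data
    generators (expert rating panels that hit target consensus
    summaries, patient cohorts with planted ground-truth flags, and
    reference-list incidence tables).
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
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
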