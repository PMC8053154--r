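Package: coughwatch
Title: Cough-Count Telemonitoring Alerts for COPD Exacerbations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Count-level analysis pipeline for domiciliary cough
    telemonitoring in chronic obstructive pulmonary disease (COPD).
    Maps noon-to-noon daily cough counts onto a variance-stabilising
    logarithmic scale (the B-scale), estimates individualised baselines,
    generates exacerbation early-warning alerts from cough deviations and
    from a weighted daily symptom questionnaire, detects and windows
    treated exacerbation episodes from medication and hospital records,
    and evaluates alert strategies by success rate, false alarm rate and
    lead time. Includes a seeded synthetic cohort generator with
    overdispersed daily counts whose standard deviation is linear in the
    patient mean, prodromal count elevation before treatment onset, and
    questionnaire responses coupled to exacerbation state, so the whole
    pipeline can be exercised end to end without patient data.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
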