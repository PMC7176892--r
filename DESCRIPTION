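Package: mhqtools
Title: Computable Phenotyping and Synthetic Cohorts for a Branching
    Mental Health Questionnaire
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Models a branching mental-health questionnaire (screening
    items with skip rules), derives likely lifetime and current
    mental-disorder syndromes from coded responses (CIDI-SF style
    lifetime depression and generalised anxiety, one-week
    hypomania/mania, AUDIT hazardous/harmful drinking, six-item PTSD
    checklist, unusual experiences, self-harm and self-reported
    addiction), gates a likely bipolar-affective-disorder label on
    depression history, combines outcomes into five mood-disorder
    groups, derives risk-factor screens, and produces comorbidity and
    characteristics tables. A synthetic-cohort generator with known
    latent syndrome states, pairwise comorbidity structure and
    configurable item fidelity and nonresponse supports end-to-end
    validation without access to restricted survey data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
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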