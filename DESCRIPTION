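Package: migrainecua
Title: Markov Cohort Cost-Utility Analysis of Quarterly Anti-CGRP Migraine Prevention
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: A six-state Markov cohort model for cost-utility analysis of
    preventive migraine treatment (intravenous eptinezumab versus placebo)
    from a health-payer perspective over a six-month horizon. Health states
    are monthly-migraine-day (MMD) severity bands; quarterly cycles carry
    state- and arm-specific utilities and costs with 3% annual discounting.
    Includes bootstrap estimation of transition matrices from patient-level
    longitudinal MMD panels, a seeded synthetic trial-cohort generator,
    one-way (tornado) deterministic sensitivity analysis, and probabilistic
    sensitivity analysis with cost-effectiveness acceptability curves.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
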