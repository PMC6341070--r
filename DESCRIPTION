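Package: coexscreen
Title: Seed-Gene Co-Expression Screening Across Expression Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Genome-wide screening of genes whose expression tracks a
    designated seed gene across multiple independent expression cohorts.
    Provides per-cohort simple linear-regression association statistics,
    tiered direction-consistent multi-cohort candidate filters, replication
    and direction-consistency reports in validation groups, tumor-versus-
    normal association-specificity classification, antimode expression
    dichotomization with Kaplan-Meier / log-rank survival screening, and a
    ground-truth synthetic-cohort generator for end-to-end testing of the
    whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    survival,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
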