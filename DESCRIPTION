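Package: npcmolclass
Title: Genetic Subtype Classification and Survival Analysis for Nasopharyngeal Carcinoma Cohorts
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for molecular classification of nasopharyngeal carcinoma
    (NPC) cohorts from somatic mutation and copy-number data. Reads MAF-like
    mutation tables, SEG copy-number segments, BED gene models and clinical
    tables; calls gene-level amplifications and deletions from segment log2
    ratios with strict thresholds; computes tumor mutation burden; assigns
    each tumor to one of three genetic subtypes (RAS/PI3K/AKT, cell-cycle,
    unclassified) via an ordered decision tree; and evaluates subtype
    prognostic value with Kaplan-Meier estimates, log-rank tests and Cox
    proportional-hazards models. A synthetic-data module generates a
    deterministic 82-patient fixture cohort and stochastic simulated cohorts
    so the full pipeline can be exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    survival,
    stats,
    graphics,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
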