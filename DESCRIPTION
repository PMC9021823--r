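Package: izofr
Title: Individual Zones of Optimal Functioning for Performance Anxiety Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates per-individual zones of optimal functioning (IZOF) from
    repeated measurements of multidimensional state anxiety (CSAI-2 subscales:
    cognitive anxiety, somatic anxiety, self-confidence) linked to judged
    performance scores. Provides trimmed judge-panel aggregation, item-level
    questionnaire scoring, zone estimation as the mean subscale intensity at
    personal-best performances plus or minus half the within-person standard
    deviation, retrospective validity statistics (outstanding-performance
    threshold, in-zone versus out-of-zone score difference, correct
    classification rates), and prospective prediction via zone-membership
    combinations and tie-aware Spearman correlation between zone distance and
    performance. A seeded synthetic-cohort generator supports parameter-recovery
    and calibration testing without participant data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
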