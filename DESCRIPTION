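Package: tapmem
Title: Digital Memory Biomarkers from Smartphone Tap-Event Logs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for smartphone-administered verbal and
    spatial memory tests. Parses and validates raw tap-event trial logs,
    derives fourteen digital biomarkers including individualized
    sensory-motor processing thresholds (iSMPT), adjusted recall
    latencies, partial-credit accuracy scores and self-correction counts,
    fits proportional-odds composite models over an ordered clinical
    impairment continuum, quality-controls Symbol Digit Modalities Test
    scores against a regression prediction envelope, and quantifies
    test-retest reliability (random-intercept ICC, variance reduction by
    trial averaging, age-normative prediction bands). A fully seeded
    synthetic cohort generator emulates the statistical structure of the
    raw data so that every stage is testable end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    lme4,
    MASS,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
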