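Package: fhpdiag
Title: Preliminary Diagnostic Models for Forward Head Posture Screening
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for screening and preliminary diagnosis of forward head
    posture (FHP) in adolescents from the forward neck tilt angle (FNTA) and
    radiographic sagittal-alignment parameters. Implements FNTA threshold
    screening into four FHP levels, per-parameter diagnostic models built from
    three linear boundary lines in the (parameter, FNTA) plane, FNTA-only
    candidate-level generation with ambiguity intervals, majority-vote
    diagnosis across the eight models, agreement and confusion-chart
    evaluation, correlation and normality reporting, and a seeded synthetic
    cohort generator with per-level truncated-normal structure so the whole
    pipeline can be exercised without patient data. Ships a published
    constants bank for the eight models and a 43-participant evaluation
    fixture.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    MASS,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
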