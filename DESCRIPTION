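Package: cogcourse
Title: Longitudinal Cognitive Course Analysis for Two-Wave Case-Control Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the long-term cognitive course of a patient
    group against healthy controls across two assessment waves. Provides
    control-baseline normative z-scoring of a neuropsychological test battery,
    theory-based domain scores and a cognitive composite, random-intercept
    linear mixed growth models with estimated marginal means, regression-based
    reliable change index (RCI) classification correcting for practice effects
    and regression to the mean, clinically-significant-impairment prevalence
    and baseline-to-follow-up transition analysis, and a seeded synthetic
    cohort generator emulating a first-episode schizophrenia study design so
    every stage of the pipeline is testable without access to clinical data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    lmerTest,
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
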