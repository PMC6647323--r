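Package: enrichsim
Title: Patient Recruitment Strategies for Two-Stage Adaptive Enrichment
    Trials with Time-to-Event Endpoints
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and planning tools for two-stage adaptive enrichment
    clinical-trial designs with time-to-event endpoints. Models a trial in an
    overall population containing a biomarker-positive subgroup, with an
    interim hazard-ratio decision rule (futility stop, continue overall, or
    enrich to biomarker-positives), confirmatory analysis by the weighted
    inverse-normal combination test with Hochberg intersection p-values under
    the closure principle, and three patient-recruitment strategies (halted
    recruitment, continued recruitment from the overall population, continued
    recruitment from biomarker-positives) compared against a non-enriched
    fixed-horizon comparator with a futility-only interim look. Includes a
    Schoenfeld sample-size calculator, uniform and truncated-exponential
    accrual models, a seeded patient-level simulator, and a Monte-Carlo
    driver producing operating characteristics (patient numbers, total trial
    period, decision and rejection probabilities, interim-estimate accuracy).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    survival,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
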