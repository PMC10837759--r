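Package: dmpkit
Title: Chronic Disease Screening and Monitoring Platform Toolkit
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale implementation of the computational core of a
    national chronic disease management platform: an HL7 FHIR R4-aligned
    patient data model with bundle readers and CarePlan export, declarative
    disease-module definitions (eligibility predicates, recall intervals,
    parameter validity periods), a care-pathway page-flow engine for
    screening and monitoring encounters, CDS Hooks-style decision support
    services including SCORE-family cardiovascular risk scoring, population
    coverage and goal-achievement statistics, and a seeded synthetic
    primary-care cohort generator so that every component is testable
    without access to a real electronic health record.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
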