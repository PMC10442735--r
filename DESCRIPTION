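Package: diabudget
Title: Budget Impact of Nurse-Supported Digital Diabetes Care with
    HbA1c-Linked Complication Risk
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A deterministic budget impact model for adding a digital,
    diabetes-nurse-educator supported care program (MyDiaCare) to standard
    of care for type 2 diabetes in the South African private sector. Cohort
    mean HbA1c levels are converted into relative risk multipliers for
    macrovascular and microvascular complications using published HbA1c
    threshold rules, annual complication incidences are adjusted
    accordingly, and per-year event counts, complication costs, monitoring
    costs and net budget impact are projected over a five-year horizon.
    Includes one-way deterministic sensitivity analysis (tornado data),
    named alternative scenarios (equal-baseline, market-share uptake), a
    patient-level clinical outcome pipeline (HbA1c change, treatment-target
    attainment, care-plan adherence), and a synthetic cohort generator that
    emulates the structure of the underlying observational study.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
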