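Package: plancheckr
Title: Automated Integrity Checking of Radiotherapy Treatment Plans
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A vendor-independent, configuration-driven rule engine for the
    physics initial chart check of external-beam radiotherapy treatment plans.
    Reads DICOM RT Plan, RT Dose and RT Structure Set files plus a structured
    sidecar file carrying planning-system fields absent from DICOM exports,
    runs a configurable battery of integrity checkers (isocenter consistency,
    naming conventions, reference-point dose limits, couch and imager
    positions, control-point and MLC deliverability, QA-plan consistency, and
    more) and reports each as pass, flag, report or manual. Also provides the
    audit statistics used to evaluate such a tool in clinical service
    (issue categorization, exact two-sided Fisher test on 2x2 tables,
    tie-corrected Mann-Whitney U with exact small-sample enumeration) and a
    seeded synthetic plan and defect generator so the entire system is
    testable without clinical data.
License: MIT + file LICENSE + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
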