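Package: polypillCEA
Title: Individual-Level Discrete-Event Cost-Effectiveness Model of a
    Cardiovascular Polypill Strategy
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Discrete-event microsimulation comparing a fixed-dose
    combination ("polypill") strategy for cardiovascular prevention with
    usual multi-pill care in an NHS-style setting. Generates a synthetic
    high-risk cohort, drives each individual through lifetime event
    histories using proportional-hazards risk engines (primary and
    secondary cardiovascular disease, incident diabetes, heart failure,
    adverse drug events) with piecewise-constant competing hazards,
    models medication adherence and cessation, accrues continuously
    discounted costs and quality-adjusted life years, and summarises
    results as incremental cost-effectiveness ratios and net monetary
    benefit with probabilistic sensitivity analysis and population
    bootstrap.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    graphics,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
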