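Package: prepcost
Title: Activity-Based Micro-Costing of Differentiated PrEP Delivery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An activity-based micro-costing engine for HIV pre-exposure
    prophylaxis (PrEP) delivery programmes, built around a comparison of
    six-month PrEP dispensing supported by interim HIV self-testing against
    standard three-month dispensing in Kenyan clinics. Reads structured
    cost-input ledgers (salaries by cadre, drug and test unit prices,
    capital, start-up, overhead and training items), summarises
    time-and-motion observation logs into per-activity and per-visit
    personnel time, annuitizes one-off costs with discounting, accrues
    variable costs against visit and client-month counts, allocates fixed
    costs across study arms, and reports per-arm cost tables, per
    client-month unit costs, cost shares, scenario projections (trial
    versus Ministry of Health delivery, with and without creatinine
    monitoring) and arm-comparison summaries. Includes a seeded synthetic
    generator for observation logs, ledgers and accruals so the full
    pipeline is testable without access to primary data.
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
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
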