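Package: copcost
Title: Indirect Cost Estimation for PEPFAR Country Operational Plan Funding
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimates the indirect (facilities and administration) costs
    embedded in PEPFAR Country Operational Plan planned-funding ledgers for
    international organizations and universities. Implements the full
    accounting chain from raw funding records to per-partner, per-agency,
    per-year estimates: partner classification with proportional allocation of
    unawarded ("NA") funding, sub-award retention rates adjusted for
    international sub-awardees, modified total direct cost (MTDC) exclusions
    (capital, vehicles, laboratory equipment, ARV procurement) with
    proportional back-fill for years lacking source data, and inversion of
    non-excludable costs into indirect costs under six negotiated-rate
    scenarios. Includes a synthetic ledger generator with known ground truth
    so every pipeline stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
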