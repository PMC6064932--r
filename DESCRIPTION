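Package: mchfundr
Title: Financial Feasibility of a Basic Maternal and Child Health Benefit Package
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Bottom-up costing of a basic maternal and child health (MCH)
    benefit package at primary health care facilities, revenue scenario
    construction for Nigeria's Basic Health Care Provision Fund (BHCPF),
    and coverage/funding-gap analysis at state level. Projects target
    beneficiary populations from census baselines, annualizes facility
    capital stock, allocates shared costs by MCH utilization weights,
    prices the benefit package from a drug and consumable price list,
    builds per-state revenue under configurable BHCPF allocation and
    counterpart-funding scenarios, and reports required amounts, lives
    covered, funding gaps and the additional-funding percentage. Includes
    a synthetic facility-register generator for end-to-end testing and
    built-in reference tables for the three study states (Imo, Kaduna,
    Niger).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    tibble,
    tidyr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
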