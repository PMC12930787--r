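Package: neosurv
Title: Neonatal Healthcare-Associated Infection Surveillance Engine
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A rule-based surveillance engine for healthcare-associated
    infections (HAI) in very-low-birth-weight and very preterm infants.
    From patient-level unit records it determines eligibility and
    follow-up, accounts patient-days and device/factor exposure days,
    assembles clinical, laboratory, imaging and microbiological findings
    into infection episodes, classifies bloodstream infections,
    pneumonia, necrotizing enterocolitis and surgical site infections
    under configurable temporal and taxonomic rules, flags
    multidrug-resistant organisms, and computes surveillance metrics:
    use rates, incidence densities, SSI rates, and the standardized
    infection ratio (SIR) against stratified reference rates. A seeded
    synthetic-cohort generator produces complete input tables with
    planted ground truth so every rule is testable without real data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
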