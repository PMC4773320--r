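Package: lymphpbpk
Title: Population Whole-Body PBPK Simulation of Subcutaneous Macromolecule
    Absorption with Lymphatic Uptake
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates the plasma time course of large molecules (a ~45 kDa
    pegylated peptide is the reference case) after subcutaneous injection in a
    virtual population of adult males. Provides an anthropometric population
    generator with lymphatic-system variability (organ, blood and lymph masses
    sampled from normal or log-normal distributions re-centered by allometric
    scaling, with derived blood/plasma/lymph flows and glomerular filtration
    rate), a whole-body physiologically-based pharmacokinetic model with a skin
    injection depot draining through a lymphatic drainage compartment sized as
    a fraction of the injection volume, non-compartmental analysis, pooled and
    two-stage estimation of the drainage volume fraction from concentration-time
    data, a synthetic first-in-human trial emulator, and one-at-a-time mean and
    distribution sensitivity analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    Matrix,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
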