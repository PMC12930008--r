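Package: milkpk
Title: Lactation Pharmacokinetics: Milk Transfer Simulation, NCA and
    Infant-Exposure Metrics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates maternal plasma and breastmilk concentration-time
    profiles for orally dosed drugs with a one-compartment first-order
    absorption model and a phase-distribution lactation module (pH
    partitioning, milk protein binding, milk-fat partitioning with dynamic
    postpartum milk pH). Provides noncompartmental analysis (Cmax, AUC,
    terminal half-life), infant-exposure risk metrics (milk-to-plasma ratio,
    daily infant dose, relative infant dose), virtual-population simulation
    with log-normal inter-individual variability, a synthetic clinical
    lactation study generator, predicted-to-observed model adequacy checks
    and milk-composition sensitivity grids. Ships a calibrated doravirine
    reference configuration.
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
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    deSolve,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
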