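Package: comxdyn
Title: ComX Quorum-Sensing Pheromone Dynamics in Bacillus subtilis Batch Fermentations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of the ComX quorum-sensing pheromone during
    surfactin-producing Bacillus subtilis batch fermentations. Implements a
    coupled linear ODE model for ComX activity and a putative ComX-specific
    protease driven by a fitted biomass curve, bounded least-squares parameter
    estimation with a recovery harness, four-parameter sigmoid and
    three-parameter exponential curve fits with analytic derivatives,
    Miller-unit bioassay arithmetic with blank screening and detection limits,
    batch-process yield and productivity metrics, peptide monoisotopic mass and
    m/z calculations for the farnesylated ComX decapeptide, and a seeded
    synthetic cultivation-data generator for validation studies.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    lhs,
    tibble,
    readr,
    withr,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
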