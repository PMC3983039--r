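Package: radcell
Title: Dynamical Models of Cellular Responses to Ionizing Radiation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and inference tools for compartment models of cell
    populations under ionizing radiation. Implements an intracellular
    "memory" model in which successfully repaired cells become transiently
    radioresistant, an inter-cellular "communication" model in which hit or
    adapted cells induce protection in bystanders, and their combination.
    Provides in-silico radioadaptation (priming/challenge) protocols,
    clonogenic dose-response curves with low-dose hyper-radiosensitivity
    (HRS) and increased radioresistance (IRR) phase classification,
    quasi-stationary state detection under continuous exposure, multi-start
    least-squares fitting of dose-survival data, and seeded synthetic-data
    generators for parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    tibble,
    dplyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    readr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml,
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
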