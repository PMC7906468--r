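Package: phenoswitch
Title: Phenotypic Heterogeneity, Treatment Scheduling and Relapse Dynamics in
    Tumour Cell Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a tumour cell population structured by a growth-rate
    trait as a linear system of growing, switching and dying subpopulations,
    under two treatment types: one whose induced mortality is proportional to
    a cell's growth rate (cell-cycle-specific chemotherapy) and one that kills
    all phenotypes at an equal rate (antibody-mediated immunotherapy).
    Provides deterministic multi-subpopulation dynamics with equilibration to
    the stable trait distribution, calibration of the trait-independent
    mortality to a matched end-of-treatment tumour load, predefined and
    adaptive sequential treatment schedules including the continuously
    reevaluated (optimal) scheme, a matched two-subpopulation stochastic model
    (exact jump-process and Langevin engines), and outcome metrics: minimum
    tumour load, relapse time, extinction probability, Shannon evenness of
    the trait distribution, and diffusion step-size statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
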