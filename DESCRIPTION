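Package: phenosel
Title: Stochastic Multi-Scale Modelling of MGMT-Mediated Temozolomide
    Resistance in Glioblastoma
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates a constant-slot population of glioblastoma cells in
    which O-6-methylguanine-DNA methyltransferase (MGMT) is constitutively
    expressed, cells grow exponentially, divide through a noisy linear
    size map with binomial partitioning of molecules, and die at a rate
    set by temozolomide (TMZ) dose and per-cell MGMT level.  Exact
    Gillespie simulation and fixed-step tau-leaping (with automatic
    fallback) drive the intracellular kinetics.  The package includes the
    three TMZ uptake regimens (step, pulse, sigmoidal), population
    statistics (noise, skewness, selection ratio, viability recovery),
    rejection approximate Bayesian computation for parameter calibration
    against growth and viability assays, and a synthetic-data generator
    emulating those assays, so that selective, dose-dependent upregulation
    of MGMT through cell death is reproducible at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
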