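Package: berrystore
Title: Storage-Quality Modelling and Multi-Objective Optimization for Fresh Wolfberry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for modelling and optimizing the post-harvest storage quality
    of fresh wolfberry (Lycium barbarum L.). Implements optimized Latin hypercube
    experimental design via an individual-based multi-objective evolutionary
    algorithm with Latin-hypercube local search, surrogate quality models
    (Gaussian radial-basis-function network, Elman recurrent network, and full
    quadratic response surface) mapping storage temperature, storage time and
    initial maturity to fruit hardness, soluble solids content, titratable
    acidity and vitamin C, factor-sensitivity decomposition (main-effect curves
    and signed Pareto term contributions), and speed-constrained multi-objective
    particle swarm optimization (SMPSO) of storage conditions with a
    crowding-bounded Pareto archive. Ships the 40-run in-study dataset and
    synthetic-data generators for end-to-end testing.
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
    jsonlite,
    lhs,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
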