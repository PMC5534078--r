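Package: hpnsim
Title: Hybrid Stochastic-Deterministic Simulation of (Coloured) Hybrid Petri Nets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Construction and simulation of generalised hybrid Petri net models of
    biochemical reaction networks. Models combine discrete places (molecule counts)
    with continuous places (concentrations) and stochastic, continuous, immediate,
    delayed and scheduled transitions. Simulation algorithms cover the exact
    jump-equation hybrid method of Haseltine and Rawlings, an accelerated variant
    that skips ODE-solver reinitialisation for independent stochastic reactions, an
    improved hybrid rejection-based method (HRSSA) with fluctuation intervals and
    propensity bounds, dynamic repartitioning, pure stochastic (Gillespie direct
    method) and pure deterministic modes, and deterministic parallel ensembles.
    Coloured hybrid Petri nets with integer-range and product colour sets unfold to
    flat nets by guard-satisfying binding enumeration. Models are read and written in
    a plain-text net description dialect and an SBML Level 2 Version 4 subset; traces
    export to CSV and plot with ggplot2.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    parallel,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
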