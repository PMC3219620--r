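Package: striatnet
Title: Striatal Network Simulation and Input-Correlation Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a recurrent inhibitory network model of the striatum:
    conductance-based leaky integrate-and-fire medium spiny neurons (MSNs) and
    fast-spiking interneurons (FSIs) with alpha-function synapses, driven by
    independent Poisson background and by correlated cortical spike ensembles
    generated as multiple-interaction processes (MIP). Provides generators for
    correlated Poisson spike trains with controllable within-pool and
    between-pool correlation, a fixed-step clock-driven network integrator with
    delayed feedforward and feedback inhibition and non-spiking membrane
    potential clones, activity statistics (population firing rates, Fano-factor
    synchrony index, signal-to-noise ratio, PSTHs, free membrane potential
    correlation and fluctuation measures), and seeded experiment pipelines for
    inhibition-regime maps, input-correlation sweeps, correlated feedforward
    inhibition, and two-group stimulus competition.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
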