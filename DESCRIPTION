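Package: boutonsim
Title: Stochastic Simulation of Calcium Handling and Neurotransmitter
    Release in a Hippocampal Presynaptic Bouton
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A hybrid stochastic-deterministic simulator of a CA3
    presynaptic terminal. Couples a four-compartment calcium model of
    the bouton (cytosol, ER, IP3-receptor and active-zone microdomains)
    with Markov-chain gating of IP3 receptors and Cav2.1 voltage-gated
    calcium channels, Hodgkin-Huxley membrane excitability, and a
    dual-sensor model of synchronous, asynchronous and spontaneous
    vesicle fusion with release-site refractoriness. Ships wild-type and
    familial Alzheimer's disease (3xTg-AD) parameterizations of IP3
    receptor gating and IP3 metabolism, experiment drivers for single
    action potentials, paired pulses, 20 Hz trains and calcium clamps,
    and stimulus-release synchrony metrics based on the Kuramoto order
    parameter. All results are returned as tidy tibbles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
LinkingTo: Rcpp
Imports:
    Rcpp,
    deSolve,
    dplyr,
    generics,
    ggplot2,
    graphics,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
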