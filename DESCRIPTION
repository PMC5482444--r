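Package: chemoevolve
Title: Run-and-Tumble Chemotaxis Strategies in Stochastic Attractant Fields
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Agent-based simulation of run-and-tumble bacterial chemotaxis
    driven by a bilobed linear-response kernel, in stochastic spectral
    attractant fields with tunable correlation time and length. Provides
    fitness evaluation by time-to-threshold attractant uptake,
    Metropolis-Hastings evolutionary optimization of response parameters
    under adaptive, inverted and speculator strategy constraints, kernel
    fitting to tumbling time courses, and diagnostic experiments
    (step responses, oscillating two-Gaussian worlds, 3D traversal
    autocorrelation). Simulation cores are implemented in C++ via Rcpp;
    results are returned as tibbles with broom-style tidiers and ggplot2
    autoplot methods.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE, load = "source")
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
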