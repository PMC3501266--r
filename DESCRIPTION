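Package: neuralpulse
Title: Traveling Pulses in Deterministic and Stochastic Neural Fields
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis and simulation toolkit for a one-dimensional scalar
    neural field with an offset Mexican-hat (difference-of-exponentials)
    connectivity kernel, a continuum model of direction selectivity.
    Provides closed-form construction of freely propagating and
    stimulus-locked traveling pulses from the threshold-crossing
    conditions, Evans-function linear stability with the essential
    spectrum, stimulus-locking tongue diagrams, Euler-Maruyama
    integration of the Langevin field with Stratonovich multiplicative
    noise, level-set tracking of wave position across trial ensembles,
    and the perturbative wandering theory: effective diffusivity of the
    Brownian displacement of free pulses and the Ornstein-Uhlenbeck
    relaxation rate of stimulus-locked pulses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    minpack.lm,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests: testthat (>= 3.0.0), optparse, jsonlite, deSolve, withr
Config/testthat/edition: 3
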