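Package: mmndcm
Title: Dynamic Causal Modeling of the Auditory Mismatch Negativity
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation and Bayesian inversion of a five-source canonical
    microcircuit neural-mass model of auditory evoked responses. Provides a
    synthetic duration-deviant oddball paradigm with planted group effects on
    superficial-pyramidal gain, a sensor-space preprocessing chain (common
    average reference, Butterworth filtering, downsampling, epoching, ICA
    ocular correction, amplitude-based trial rejection, robust averaging,
    grand averages), an analytic multi-shell spherical head forward model with
    spatial-mode reduction, variational Laplace model inversion with a
    free-energy approximation to log model evidence, fixed-effects Bayesian
    model selection over factorial model spaces, and an end-to-end study
    driver for 2 x 3 (condition by group) factorial analyses of the mismatch
    negativity.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    signal,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pracma,
    ggplot2
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
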