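Package: spikemoments
Title: Mean-Field and Finite-Size Moment Equations for Globally Coupled
    Spiking Phase Neurons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Three consistent levels of description for a globally coupled
    network of N spiking phase neurons driven by a shared exponentially
    filtered synaptic drive: an exact event-driven microscopic simulator (with
    a dense fixed-step reference integrator), the N -> infinity mean-field
    (Vlasov advection plus Wilson-Cowan reduction) solvers, and the order-1/N
    generalized activity equations that propagate the mean drive, the phase
    density, and the equal-time covariances (drive variance, drive-density
    cross covariance, and the two-point density covariance) as a closed PDE
    system. A seeded Monte-Carlo ensemble engine estimates the same moments
    empirically and serves as the ground-truth oracle for the deterministic
    solvers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    deSolve,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
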