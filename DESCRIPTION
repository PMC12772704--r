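Package: recipnet
Title: Complexity and Dynamics of Partially Symmetric Random Recurrent Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how the correlation between reciprocal synaptic
    weights shapes the phase-space structure and dynamics of random recurrent
    rate networks. Provides a generator for Gaussian connectivity ensembles
    with prescribed reciprocal correlation, the limiting elliptic spectral law
    and its logarithmic potential, closed-form and Monte-Carlo estimates of
    topological complexity (the exponential growth rate of the expected number
    of fixed points), a fixed-step integrator for the rate dynamics with
    tangent-space Lyapunov exponents, participation-ratio dimensionality,
    activity statistics, transient path lengths, Newton fixed-point searches,
    and desk-scale parameter-sweep drivers that emit tidy result tables.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    Rcpp,
    jsonlite
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
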