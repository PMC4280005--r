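Package: fluxspline
Title: Dynamic Metabolic Flux Analysis with Free-Knot B-Spline Flux Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Estimates smooth, specific metabolic flux profiles from time-course
    measurements of extracellular concentrations and exchange fluxes. Free fluxes
    of a stoichiometric network under the pseudo-steady-state assumption are
    parameterized as clamped quadratic B-splines with free internal knots; the
    resulting dynamic least-squares problem is discretized by orthogonal
    collocation on finite elements (Radau points) and solved through an
    incremental algorithm that inserts knots one at a time under small-sample
    corrected Akaike (AICc) control, extends the horizon measurement by
    measurement, and warm-starts every subproblem via profile-preserving knot
    insertion and spline prolongation. Supports rational, orthonormal and
    optimized null-space bases, a chi-square goodness-of-fit gate, Monte-Carlo
    bootstrap confidence bands, and generators for batch and
    dilution-controlled continuous bioreactor experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    Rcpp,
    rlang,
    splines,
    stats,
    tibble,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
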