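Package: agepp
Title: Age-Structured Predator-Prey Dynamics with Role Reversal
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of a predator-prey system in which the
    predator population carries an explicit age structure and the trophic
    roles reverse with age: adult predators eat the prey while the prey eats
    juvenile predators. The predator age density evolves by a renewal
    (transport) equation of Kermack-McKendrick type whose birth and death
    rates depend on the prey population size, coupled to a logistic-type prey
    ordinary differential equation. The package provides the
    characteristics-aligned first-order finite-difference solver for the
    coupled system, reductions to age-averaged ordinary and delayed
    differential equation models, Newton-based equilibrium location with
    finite-difference Jacobians, Poincare-map limit-cycle detection solved by
    Levenberg-Marquardt, and a parameter-study pipeline built on Latin
    hypercube sampling, attractor classification, multiclass Fisher linear
    discriminant analysis, and phase/bifurcation diagrams in the
    maturation-age/juvenile-predation plane.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    deSolve,
    lhs,
    minpack.lm,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    MASS,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
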