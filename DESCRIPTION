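Package: mpfrap
Title: Multiphoton Fluorescence Recovery After Photobleaching with Shear Flow
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Closed-form recovery models for multiphoton fluorescence recovery
    after photobleaching (MPFRAP) under pure diffusion, diffusion with uniform
    convection, and diffusion in laminar shear flow; a lattice Monte Carlo
    simulator of photobleached-molecule transport that generates recovery
    curves; a seeded, bounded Levenberg-Marquardt fitting pipeline that
    extracts diffusion coefficients from recovery curves; and an evaluation
    harness that maps fit accuracy over scaled-velocity/scaled-shear
    parameter space.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    minpack.lm,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml,
    ggplot2
Config/testthat/edition: 3
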