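Package: pamech
Title: Pipette Aspiration Micromechanics of Embryonic Ventricular Walls
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of micropipette-aspiration stiffness tests on embryonic
    ventricular walls. Normalizes recorded pressure/deflection traces into
    load-deflection curves, computes the strain-energy-density stiffness
    metric by trapezoidal integration, and compares cohorts with one-way
    ANOVA plus Tukey post-hoc tests and genotype t-tests. Includes an
    axisymmetric large-deformation finite-element forward model of the
    aspiration test on a bilayer (compact/trabecular) wall with a
    nearly-incompressible neo-Hookean constitutive law in a mixed
    displacement-pressure formulation, inverse identification of the
    small-strain tangent modulus by least-squares curve matching,
    morphometry utilities for cleared-tissue image stacks, and a
    synthetic-data generator so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    stats,
    tiff,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
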