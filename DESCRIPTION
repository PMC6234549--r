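Package: tacfit
Title: Compartmental Kinetic Modelling of Dynamic PET Time-Activity Curves
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Plasma-input pharmacokinetic quantification of dynamic brain PET
    studies with reversible and irreversible one- and two-tissue compartment
    models, optional fractional blood volume and an irreversible vascular
    trapping component. Builds metabolite-corrected arterial parent-plasma
    input functions from sampled blood data, fits regional time-activity
    curves by weighted nonlinear least squares with multistart initialisation,
    compares models by the Akaike information criterion, gates parameter
    estimates by their percent standard deviation, and derives the volume of
    distribution and non-displaceable binding potential. Includes a synthetic
    cohort generator emulating a two-genotype case-control neuroinflammation
    study and the accompanying nonparametric group statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    minpack.lm,
    lhs,
    jsonlite,
    yaml,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    withr
Config/testthat/edition: 3
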