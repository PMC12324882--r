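Package: coroflow
Title: Helical Flow and Wall Shear Descriptors for Coronary Haemodynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-processing toolkit for time-resolved coronary artery
    haemodynamics. Computes bulk helical-flow descriptors (h1-h4) and local
    normalized helicity from velocity/vorticity fields on unstructured
    volume meshes, wall shear descriptors (time-averaged endothelial shear
    stress, oscillatory shear index, relative residence time) with
    adverse-exposure area fractions, centerline differential geometry
    (average absolute curvature, torsion, diameters, stenosis delineation),
    allometric inflow scaling and diameter-exponent flow splits for
    boundary conditions, Carreau-Yasuda blood rheology, and a
    normality-gated nonparametric statistical comparison workflow with
    Holm correction. Ships analytic flow phantoms (swirling pipe flow,
    reversal wall-shear series, helical and stenosed centerlines, copula
    group samples) with closed-form ground truth so the whole pipeline is
    testable without external CFD data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    xml2
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
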