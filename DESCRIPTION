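Package: astigvec
Title: Vector Analysis of Astigmatism for Toric Intraocular Lens Cohorts
Version: 0.1.0
Authors@R: person("astigvec", "maintainers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Double-angle vector algebra for refractive and corneal
    astigmatism, Naeser polar-value (Rx/Ry) decomposition, ocular residual
    astigmatism by vector subtraction after spectacle-to-corneal plane
    conversion, paired univariate and bivariate (Hotelling T-squared)
    longitudinal comparison, simulation-based power analysis, double-angle
    plots with centroids and confidence ellipses, and a synthetic toric-IOL
    cohort generator for end-to-end pipeline testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    graphics,
    grDevices,
    utils,
    jsonlite,
    optparse,
    readxl
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
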