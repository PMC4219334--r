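Package: nngibbs
Title: Gibbs Nearest-Neighbor Interaction Analysis for Spatial Point Patterns
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers the effective interaction potential that best explains the
    spatial distribution of one set of point-like objects relative to a
    reference set, generalizing object-based colocalization analysis.
    Nearest-neighbor distance distributions are compared against a grid-sampled
    "context" density that corrects for the layout of the reference set and the
    shape of the admissible region; the observed distribution is modeled as the
    context deformed by a Boltzmann factor exp(-phi(d)) under a Gibbs
    nearest-neighbor model. Provides parametric potential families (step,
    Hernquist, linear, Plummer) and a penalized non-parametric piecewise-linear
    potential, Monte Carlo rank tests for the significance of an inferred
    interaction, feature-point detection of blob-like objects in 2D/3D
    fluorescence images, and synthetic data generators for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    grDevices,
    graphics,
    utils,
    jsonlite,
    tiff
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
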