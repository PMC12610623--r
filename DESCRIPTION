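Package: rnpquant
Title: Quantitative Analysis of Fluorescently Labeled Cas9 Delivery Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the quantitative readouts of CRISPR ribonucleoprotein
    (RNP) delivery studies in cultured cells. Implements fluorescence
    correlation spectroscopy (FCS) analysis end to end: multi-tau and direct
    autocorrelation of photon-arrival streams, fitting of a two-component
    diffusion model with a triplet term, focal-volume calibration against
    reference dyes, and conversion of diffusion correlation times to
    diffusion coefficients and Stokes-Einstein hydrodynamic radii. Also
    provides confocal two-channel z-stack axial-offset quantification
    (per-ROI peak-slice differences), reagent dosimetry (per-cell dose,
    molar-to-mass conversion, BCA linear calibration, immobilization mass
    balance), and synthetic-data generators with known ground truth:
    Brownian-dynamics photon streams from a 3D Gaussian focal volume with
    optional triplet blinking, and two-channel Gaussian-blob z-stacks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    tiff,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
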