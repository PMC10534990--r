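Package: beadpcr
Title: Bead-Compartment Digital PCR: Segmentation, Poisson Quantification,
    and Binding Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for digital PCR performed in DNA-binding
    hydrogel bead compartments. Detects beads in fluorescence well images
    with a maximally-stable-extremal-regions segmentation step and a
    spherical fluorescence model, classifies beads as PCR-positive or
    -negative with a Gaussian-mixture/BIC threshold, and converts negative
    fractions into absolute target concentrations with bead-count-based
    Poisson statistics that require no compartment-volume measurement.
    Includes Langmuir isotherm and adsorption-kinetics fitting with
    confidence intervals, equilibrium capture-fraction prediction,
    Deming regression and Bland-Altman method comparison, and a synthetic
    data generator that emulates bead monolayer images, binding assays,
    and paired method measurements with ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    minpack.lm,
    jsonlite,
    stats,
    utils,
    tiff
Suggests:
    testthat (>= 3.0.0),
    mclust,
    png
Config/testthat/edition: 3
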