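Package: tubecurv
Title: Curvature Sensing and Induction Analysis for Membrane Nanotubes and
    Buckled Bilayers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantification of protein curvature sensing and curvature
    induction on model membranes. Implements the sorting-ratio analysis of
    two-channel confocal images of giant unilamellar vesicles (GUVs) with
    optically pulled membrane nanotubes (Otsu segmentation, background
    subtraction, sorting ratio S), tube-radius estimation from membrane
    fluorescence with a tension/force calibration of the conversion constant
    k_tub, fluorophore standard-curve calibration of protein surface density,
    and time-course analysis of protein-driven curvature induction. A second
    analysis arm estimates local mean curvature on buckled bilayers from
    lipid headgroup coordinates via a periodic two-dimensional Fourier height
    field and its shape operator, builds equilibration-gated curvature
    preference histograms of a membrane-inserted probe against random lipid
    positions, and measures insertion depth relative to the phosphate level.
    A synthetic-data module generates ground-truthed microscopy frames,
    calibration tables and buckled-membrane coordinate sets so that every
    stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    EBImage,
    ggplot2,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
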