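Package: phasekin
Title: Pixel-Level Kinetics and Lattice Metrology of Crystal Solid-Solid Phase Transitions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipelines for ligand-triggered solid-solid phase
    transitions in molecular (RNA riboswitch) crystals imaged by polarized
    video microscopy (PVM) and atomic force microscopy (AFM). Extracts
    per-pixel birefringence intensity traces from time-lapse video, detects
    transition events as Gaussian-fitted peaks in the negated intensity
    derivative, classifies events into transitions by k-means, and
    quantifies spatiotemporal synchrony by superpixel resampling across
    sampling-area sizes. Measures surface unit-cell constants from AFM
    topographs via 2D autocorrelation with sub-pixel peak refinement,
    including mixed-phase images and c-axis time series. A synthetic-data
    module generates both input types with known ground truth so every
    stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tiff,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
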