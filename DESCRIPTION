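Package: iceringr
Title: Ice-Diffraction Contamination in Macromolecular Crystallography
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Detection, quantification and classification of ice-diffraction
    contamination in biomolecular crystallography data. Computes Ice Finder,
    Depletion and Observation score tracks from deposited structure-factor
    intensities, condenses them into generalized-extreme-value calibrated
    p-values, and classifies detected ice as hexagonal or
    stacking-disordered. Also regenerates ice powder-ring tables from
    lattice parameters with extinction rules, fits hexagonal/cubic mixtures
    to 1D powder patterns, estimates crystallite sizes via integral breadths
    and the Scherrer equation, finds isolated ice spots on 2D frames, and
    simulates Wilson-statistics reflection sets and frames with known ground
    truth for calibration and testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
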