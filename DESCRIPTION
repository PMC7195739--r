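Package: cox2quant
Title: Kinetic and In Situ Quantification of Inducible Cyclooxygenase-2 Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantification machinery for PET studies of inducible
    cyclooxygenase-2 (COX-2) and companion fluorescent in situ hybridization
    (FISH) readouts. Provides reversible compartment-model simulation of
    regional time-activity curves, metabolite-corrected arterial input
    functions, Logan graphical estimation of distribution volume (V_T),
    Lassen occupancy plots with nondisplaceable volume (V_ND) estimation,
    binding potential and SUV-based outcome measures, and an RNAscope-style
    image pipeline (watershed nuclear segmentation, spot detection,
    dual-channel autofluorescence exclusion, per-cell transcript scoring).
    Synthetic-data generators with known ground truth support end-to-end
    validation of both the kinetic and the image stages.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    pracma,
    jsonlite,
    yaml,
    withr,
    EBImage,
    tiff
Suggests:
    testthat (>= 3.0.0),
    deSolve
Config/testthat/edition: 3
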