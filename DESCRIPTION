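Package: platesim
Title: Simulation and Quantification Toolkit for Automated Perfusion
    Cell-Culture Platforms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A desk-scale toolkit for automated multi-well cell-culture
    platforms that formulate media by microfluidic pulse-width modulation
    (PWM) and exchange it by programmed empty/fill/level cycles. Provides a
    discrete-event fluidics simulator with per-well volume and solute-mass
    ledgers, a PWM valve scheduler that converts target concentration
    profiles into quantized pulse plans, a fluorescence quantification
    pipeline (darkfield/flatfield correction, ROI medians, linear
    calibration and inversion to concentrations), gastruloid morphometrics
    (maximum-entropy segmentation, elongation index via the largest
    inscribed circle, ten-segment posterior-to-anterior expression
    profiles, condition-level polynomial fits and Welch tests), and seeded
    synthetic-data generators with attached ground truth so the whole
    pipeline is testable without an instrument.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    pracma,
    tiff,
    yaml,
    jsonlite,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
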