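Package: gripforce
Title: Grip Strength Estimation from Forearm Muscle Deformation Sensing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for force-myography grip
    strength estimation at multiple wrist angles. Provides a synthetic
    sensor-physics generator for a 12-channel photoresistor muscle
    deformation array with three Hall wrist-angle channels (saturating
    response curve, 10-bit ADC quantization, configurable noise), signal
    preprocessing (moving-average filtering, min-max normalization, 200 ms
    window stitching, stratified splitting), a seeded time-series 1-D
    convolutional network for three-class wrist-angle recognition, an
    angle-conditioned Voigt viscoelastic grip model fitted by linear least
    squares, and evaluation tools (RMSE, correlation, confusion matrices)
    with a reproducible end-to-end experiment driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ggplot2,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    MASS,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
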