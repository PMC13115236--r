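Package: beandry
Title: Coffee Drying Kinetics and Hyperspectral Cup-Score Chemometrics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Coupled analysis of thin-layer coffee drying and Vis-NIR
    hyperspectral sensory prediction. Estimates moisture-transport
    parameters (first eigenvalue, Biot number, effective moisture
    diffusivity, convective mass-transfer coefficient) from drying
    curves via the first-term Fickian sphere solution, fits Arrhenius
    temperature dependence of the transport coefficients, preprocesses
    hyperspectral reflectance cubes (white/dark calibration, Otsu ROI
    segmentation, median spectra, absorbance conversion, Savitzky-Golay
    smoothing), and models cup score from absorbance spectra by NIPALS
    partial least squares regression with VIP-based wavelength
    selection. Includes seeded synthetic generators for drying curves,
    hyperspectral cubes and sensory tables so the whole pipeline is
    testable without proprietary data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    signal,
    withr
Config/testthat/edition: 3
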