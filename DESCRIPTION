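Package: photoacclim
Title: Kinetic and Spectral Analysis of Extreme-Light Acclimation in
    Green Algae
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantitative toolkit for characterising photosynthetic
    acclimation of Chlamydomonas reinhardtii to extreme light:
    Randall-Wilkins first-order thermoluminescence glow-curve simulation
    and band analysis, first-order kinetic fitting of charge
    recombination and photoinhibition, a damage-repair equilibrium model
    for photosystem II activity, chlorophyll fluorescence induction
    (OJIP) and 77 K emission-spectrum feature extraction, pigment
    quantification by the Wellburn equations, singlet-oxygen (SOSG)
    slope statistics, and growth threshold-crossing summaries. A
    synthetic instrument-data generator with "control" and "EL"
    (extreme light) presets produces realistic fixtures for every assay
    so the full analysis pipeline runs and is tested without external
    data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    minpack.lm,
    stats,
    utils
Suggests:
    deSolve,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
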