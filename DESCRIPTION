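Package: enosedx
Title: Electronic-Nose Screening Pipeline for Urinary Volatilome Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for metal-oxide-semiconductor (MOS) electronic-nose diagnostics of
    urine headspace: power-law gas calibration (Rs = A*C^alpha) with shipped Figaro
    TGS sensor constants, voltage-curve filtering and characteristic-point feature
    extraction (32-parameter instances: point voltages, slopes, differences, ppm
    estimates, distribution statistics and a sensor/socket identifier), a redundancy
    cohort builder with patient-disjoint train/test splits, a class-weighted multilayer
    perceptron classifier trained by stochastic gradient descent with momentum, confusion
    matrix evaluation, and a seeded synthetic-curve generator emulating the acquisition
    format so the full pipeline is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    nnet,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
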