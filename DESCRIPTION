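Package: pcdrad
Title: Spectral Radiography Simulation and Material Decomposition with
    Photon-Counting Detectors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end simulation of spectral (multi-threshold) chest
    radiography with a CdTe photon-counting detector, and evaluation of
    basis-material decomposition algorithms. Provides digital LucAl/IEC-style
    phantoms, a polychromatic Beer-Lambert forward model, a parametric
    detector response with charge sharing and Poisson noise, three
    decomposition regressors (second-degree polynomial, multilayer
    perceptron, support vector regression) trained on calibration grids, and
    quantitative (per-insert bias/RMSE) plus task-based (EFROC low-contrast
    detectability with a matched-filter observer) figures of merit.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
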