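Package: vesseldist
Title: Vessel Distance Analysis of Hypoxia and Proliferation Gradients in
    Tissue Sections
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies tumor hypoxia and proliferation gradients in
    multiplexed immunofluorescence tissue sections by vessel distance
    analysis: watershed nuclei segmentation with physical-unit area
    filters, simulated cell bodies, rule-based region-of-interest maps,
    exact Euclidean distance transforms to perfused vessels, all vessels
    and necrosis, pixel-level and cell-level positivity classification,
    distance-binned marker statistics with gradient slopes, scatterplot
    gating with permutation tests, and control-point similarity
    registration. Includes a synthetic tumor-phantom generator with a
    steady-state oxygen diffusion-consumption solver that provides ground
    truth for validating every analysis stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    Rcpp,
    jsonlite,
    png,
    tiff,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    deSolve,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
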