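Package: sietflux
Title: Ion Flux Estimation from Scanning Ion-Selective Electrode Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Analysis pipeline for the Scanning Ion-selective Electrode
    Technique (SIET): two-point Nernst calibration of ion-selective
    microelectrodes, reference-site correction of voltage gradients measured
    in the unstirred layer next to an epithelium, conversion of corrected
    gradients to concentration gradients, and Fick's-first-law estimation of
    transepithelial Na+ and K+ fluxes, with region-wise summaries and
    ANOVA/Bonferroni treatment comparisons. Includes a synthetic-scan
    generator that emulates the electrode physics (Nicolsky-Eisenman
    response with finite selectivity, linear drift, Gaussian sampling noise)
    and the move-wait-sample measurement protocol, so the whole chain can be
    validated by parameter recovery without instruments.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    ggplot2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
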