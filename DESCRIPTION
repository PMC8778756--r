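Package: decellwatch
Title: Non-Destructive Monitoring of Whole-Organ Decellularization from
    Image Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to monitor perfusion decellularization of whole organs
    without destructive sampling. Implements an optical "spectrometer"
    metric (per-cycle mean heart-pixel luminance of a rotating-organ image
    sequence), plateau-onset detection by a consecutive-difference rule
    shared with DNA and total-protein release curves, weak labeling of
    frames into eleven progress classes around the detected plateau, a
    compact convolutional classifier trained on the weakly labeled frames,
    and a rolling-window completion metric (0-100 percent) with a
    completion decision and optical-versus-analyte correlation. Includes a
    synthetic-session generator with ground truth (heart masks, washout
    state, true plateau time) emulating the undeposited acquisition data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    Rcpp,
    jsonlite,
    png,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
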