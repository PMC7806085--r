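Package: palpassist
Title: Tumor Detection Assistance from Temporal Tactile-Sensor Output
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Detection assistance for computer-aided laparoscopic palpation.
    Segments the temporal output of a single-element tactile sensor with a
    three-hidden-layer feed-forward network trained from scratch (He
    initialization, Adam, mini-batch backpropagation), fuses overlapping
    sliding-window outputs into per-sample tumor probabilities, reduces each
    scan trial to a representative score, calibrates the detection criterion
    from an accuracy-versus-criterion curve, and evaluates potential
    sensitivity with signal-detection theory (ROC curves and trapezoidal area
    under the curve). Includes within-participant and across-participant
    cross-validation protocols and a synthetic phantom-scan generator so the
    whole pipeline is testable end to end without recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports: graphics, signal, stats, utils
Suggests: testthat (>= 3.0.0), pROC, withr, yaml, jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
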