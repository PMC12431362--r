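Package: nibgm
Title: Non-Invasive Blood Glucose Estimation from Multi-Path Vis-NIR
    Absorbance and Photoplethysmography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analytics for wearable non-invasive blood glucose monitoring from
    multi-wavelength, multi-path visible/near-infrared finger-clip recordings.
    Computes differential absorbances across source-detector separations,
    extracts heart-rate, Kaiser-Teager energy and log-energy features from the
    transmitted photoplethysmogram, and fits a spatiotemporal multimodal fusion
    model that combines a multilayer-perceptron encoding of the optical feature
    vector with a stacked long short-term memory encoding of glucose history,
    trained end-to-end with Adam. Includes recursive multi-step forecasting,
    Parkes consensus error-grid analysis, random and day-grouped
    cross-validation, classical regression baselines, an ablation harness, and
    a seeded acquisition simulator that plants recoverable optical and
    physiological structure for fully self-contained validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    signal,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    e1071,
    ranger,
    xgboost,
    pracma,
    optparse
Config/testthat/edition: 3
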