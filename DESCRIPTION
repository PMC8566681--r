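Package: oxistab
Title: Accelerated Oxidative-Stability Testing and Shelf-Life Prediction for Pressed Seed Oils
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating ambient shelf-lives of cold- and expeller-pressed
    seed oils from accelerated oxidation tests. Detects oxidation induction
    periods on oxygen-pressure decay curves by the two-tangent method, fits the
    zero-order log-linear temperature law (OSI convention) and extrapolates
    shelf-lives to ambient temperature, computes calculated iodine values and
    saturation-class aggregates from fatty-acid compositions, and fits
    correlation screens and grouped multiple-regression shelf-life prediction
    models. Includes a seeded simulator of oxygen-pressure curves with
    closed-form ground-truth induction periods for validating the detection and
    kinetics stages, and packaged reference tables for ten expeller-pressed oils.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
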