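Package: circaskin
Title: Circadian Rhythm Detection and Single-Sample Clock Phase
    Prediction from Skin Gene Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for discovering and evaluating gene-expression biomarkers
    of circadian clock phase in human skin. Implements cosinor rhythm
    detection with per-participant meta-integration, clock-strength scoring
    of sample groups by permutation Mantel statistics on clock-gene
    correlation matrices, an oscillation-maximizing down-sampling selector,
    circular ordering of unstamped population samples with a circular
    bottleneck autoencoder, sparse principal-component training of a
    periodic single-sample phase predictor, and circular-error evaluation.
    A synthetic-data generator emulates the hybrid longitudinal plus
    population two-layer skin design with known ground-truth phases so the
    whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan
Config/testthat/edition: 3
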