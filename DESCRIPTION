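Package: pcgemotion
Title: Emotion Recognition from Heart Sound Recordings
Version: 0.1.0
Authors@R: person("PCG", "Maintainers", email = "maintainers@example.org",
    role = c("aut", "cre"))
Description: Toolkit for emotion recognition from phonocardiogram (PCG)
    recordings. Segments heart sounds into S1/S2 events, derives two
    beat-interval indicators (heart-sound HRV from successive S1 midpoints
    and the diastole-to-systole duration-ratio series), extracts linear and
    lagged-Poincare nonlinear features, and classifies emotions on valence,
    arousal and combined valence-arousal axes with a genetic-algorithm
    wrapped support-vector classifier. Includes a synthetic PCG generator
    with ground-truth annotations for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
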