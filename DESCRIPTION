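Package: gaitmark
Title: Markerless Gait Kinematics and Two-System Agreement Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for video-based markerless gait analysis from 2D pose
    landmarks in the 33-point BlazePose topology. Computes sagittal-plane
    knee flexion-extension and ankle dorsi-plantarflexion angles from
    hip-knee-ankle-toe landmark triples, corrects radial lens distortion,
    segments gait cycles on knee-flexion peaks, aggregates per-cycle maxima,
    minima and range of motion through session and subject means, and
    compares two measurement systems (e.g. a markerless pipeline against a
    wearable inertial reference) with normality-gated paired tests, Spearman
    correlation, intraclass correlation ICC(2,1), Bland-Altman limits of
    agreement and mean absolute error. Includes a planar synthetic gait
    generator with closed-form ground-truth joint-angle extrema so the whole
    pipeline can be validated without recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml,
    zoo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
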