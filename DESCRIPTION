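Package: headmotion
Title: Markerless Head-Motion Quantification from Depth-Camera Point Clouds
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Robust, regularized rigid registration of sequential face point
    clouds to a reference for markerless head-motion tracking during MRI,
    with motion-trace post-processing (triangular-window resampling, clock
    synchronization, coordinate-space mapping), pose- and trace-level motion
    metrics (head pose difference over a head-modelling ball, per-sequence
    motion scores, reference-free motion trace difference, respiration
    mutual information), a seeded synthetic-scene generator for end-to-end
    validation, and longitudinal mixed-effects analysis of session motion.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RANN,
    lme4,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
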