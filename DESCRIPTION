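Package: whisktrace
Title: Sub-Pixel Whisker Tracking in High-Speed Videos of Untrimmed Rodents
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tracks individual facial whiskers of untrimmed rodents in
    high-speed grayscale video. Frames are cleaned by brightest-pixel
    background extraction and morphological snout-silhouette removal;
    whisker centerlines are detected at sub-pixel precision by
    second-order (Hessian) ridge analysis of Gaussian derivatives;
    centerline points are grouped per whisker by density-based or
    direction-based clustering followed by collinearity stitching; each
    whisker is summarized by a four-parameter description (base position
    rho, base angle theta, bending b, length L) relative to a snout
    reference line; identities are followed over time by a
    tracking-learning-detection scheme combining a Kalman tracker, a
    one-vs-one linear support-vector-machine recognizer with sliding
    window retraining, and N-/P-expert validation, including pivot-point
    estimation from the rho-cot(theta) relation. Ships a seeded
    synthetic-video generator with full ground truth and the evaluation
    metrics (whiskers per frame, detection ratio, Savitzky-Golay based
    signal-to-noise ratio, identity consistency).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    EBImage,
    e1071,
    minpack.lm,
    png,
    Rcpp,
    signal,
    stats,
    tiff,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
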