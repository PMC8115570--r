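Package: gazevam
Title: Group-Specific Visual Attention Models from Eye-Tracking Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Learns one visual attention model (VAM) per subject group
    (case/control) from eye-tracking recordings over two-panel video
    stimuli that contrast biological and geometric motion, then
    classifies an unseen individual by comparing their per-frame
    fixation maps against each group's binary saliency maps with a
    per-frame voting rule and a Youden-index vote threshold.  Includes
    video/gaze preprocessing, motion-based frame aggregation, a
    28-channel per-pixel feature bank (steerable-pyramid subbands,
    conspicuity maps, colour, semantic and geometric channels),
    genetic-algorithm and Relief feature selection, a small
    SGD-trained neural network pixel classifier, subject-wise
    cross-validated evaluation, and a synthetic stimulus and gaze
    generator for end-to-end testing without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    png,
    yaml,
    stats,
    grDevices,
    graphics,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
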