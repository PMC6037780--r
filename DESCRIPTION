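Package: fictivemotor
Title: Classification and Mapping of Fictive Motor Patterns from
    Segmental Calcium Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Data-driven classification of fictive motor patterns
    (forward and backward peristaltic waves, anterior and posterior
    bursts, quiescence) from segmental calcium-imaging ROI traces of the
    larval Drosophila ventral nerve cord. Raw fluorescence is converted
    to a rectified running-baseline dF/F, min-max normalized, compressed
    across left/right hemisegments, decomposed into short x-t windows
    rendered as 8-bit images, embedded with pooled deep-convolutional
    features (a VGG-16 Conv4_3 tap), and clustered with Ward's
    agglomerative method; clusters are mapped to motor-pattern labels
    from their average window images. Includes per-frame label series
    with boundary compensation, event extraction and scoring against
    ground truth, behavioral statistics (frequency, intensity, left-right
    asymmetry, Markov transition matrices, end-aligned averages),
    voxel-wise Pearson correlation mapping of volumetric movies
    (behavior, dominant-pattern and seed-ROI maps with thresholded ROI
    refinement), and a synthetic fictive-locomotion generator so that
    every stage is testable without recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    tiff,
    yaml,
    jsonlite
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
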