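Package: specklegrow
Title: Subpixel Laser-Speckle Correlation Analysis of Bacterial Colony Growth
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies growth-related activity inside bacterial colonies from
    time-lapse laser speckle image sequences. The field of view is partitioned
    into small tiles; consecutive frames are compared by normalized
    cross-correlation with parabolic subpixel peak refinement, and the
    accumulated inter-frame offsets form a per-tile activity time signal.
    Moving-RMS envelopes, radial median profiles around the colony center,
    growth-arrest detection, and a multilayer-perceptron classifier separating
    growing from non-growing tile-windows complete the pipeline. A synthetic
    biospeckle simulator (band-limited circular complex Gaussian speckle with
    controlled temporal decorrelation, growing colony disks, peripheral
    activity rings, growth arrest) provides ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    tools,
    Rcpp,
    tiff,
    png,
    yaml,
    jsonlite,
    nnet,
    EBImage
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
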