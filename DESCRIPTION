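Package: ofpcanet
Title: Micro-Expression Recognition from Stacked Optical Flow with PCANet+
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A lightweight pipeline for recognizing subtle facial-motion
    classes in short video clips. Dense optical flow is estimated against
    each clip's first frame with a trajectory-subspace temporal regularizer,
    flow fields are stacked into multi-channel images with a sliding window,
    and a two-layer PCANet+ network (analytically learned PCA filter banks,
    inter-layer mean pooling, chunked binary hashing, block histograms)
    produces spatiotemporal features classified by a linear support vector
    machine under leave-one-subject-out cross-validation. Includes a
    synthetic clip generator with ground-truth displacement fields, a
    Middlebury .flo reader/writer for flow caching, and parameter-sweep
    harnesses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    e1071,
    grDevices,
    jsonlite,
    png,
    stats,
    tools,
    utils,
    yaml
Suggests:
    EBImage,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
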