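Package: drowsyhog
Title: Instantaneous Driver Drowsiness Detection with Binarized
    Shifted-Orientation HOG Features and Naive Bayes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A per-frame (instantaneous) driver drowsiness detection
    pipeline built around an improved Histogram of Oriented Gradients
    descriptor: per-cell orientation histograms are cyclically shifted
    and compared pairwise within overlapping blocks, yielding a compact
    binary descriptor that is invariant to affine illumination changes.
    Eye-state (open/closed) classification uses a from-scratch Naive
    Bayes classifier with m-estimate smoothing for binary descriptors
    and Gaussian class-conditionals for real-valued baselines. Includes
    image preprocessing (Gaussian smoothing, contrast-limited adaptive
    histogram equalization, downscaling), pluggable face/eye-region
    localization, a deterministic synthetic eye-patch generator
    emulating five recording scenarios, per-scenario evaluation
    reports, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    png,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    e1071,
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
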