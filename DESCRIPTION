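Package: ecgstress
Title: Real-Time Stress Classification from Ultra-Short Raw ECG Windows
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for 2-level and 3-level acute stress
    classification from raw, ultra-short (3 second) electrocardiogram
    windows.  Includes dataset-specific annotation pipelines for
    driving-protocol records (marker-signal peak segmentation) and for
    clip-based fear-exposure sessions (subject-based heart-rate
    annotation), baseline normalization against each subject's low-stress
    recording, central 5-minute truncation, sliding-window training-set
    augmentation, two lightweight 1D convolutional network architectures
    with heart-period-spanning kernel and pooling lengths, a seeded
    train/validation/test and k-fold evaluation protocol, and a synthetic
    stress-modulated ECG generator so that every stage can be exercised
    without access to the original recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    pracma,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
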