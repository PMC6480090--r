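Package: fallcnn
Title: Accelerometer-Based Human Fall Detection with 1D Convolutional
    Neural Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects human falls in triaxial accelerometer recordings with
    compact one-dimensional convolutional neural networks. Provides windowed
    signal ingestion and min-max normalization, rotation-based data
    augmentation of acceleration vectors, three network variants
    (CNN-3B3Conv, CNN-3Conv, CNN-1Conv) trained with stochastic gradient
    descent under a log-cosh loss, a five-metric evaluation suite (accuracy,
    precision, sensitivity, specificity, Matthews correlation coefficient),
    a synthetic fall/activity-of-daily-living signal simulator, and an
    end-to-end seeded experiment pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
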