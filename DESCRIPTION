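Package: melissoscan
Title: Pollen-Grain Detection Post-Processing, Embedding Probes and
    Evaluation for Melissopalynology
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for the detection-to-classification interface of
    microscopy pollen recognition pipelines: YOLO-format annotation I/O,
    leakage-free image-level dataset splitting and minority oversampling,
    bounding-box-consistent augmentation, IoU non-maximum suppression,
    context-aware region-of-interest expansion and cropping, embedding
    algebra (L2 normalization, cosine similarity, z-score standardization,
    cosine silhouette), a multinomial logistic-regression linear probe, and
    a full evaluation stack (greedy detection matching, F1-confidence
    curves and threshold optimization, average precision, background-aware
    detector confusion, calibration / expected calibration error).
    Synthetic slide, detector-noise, embedding-cluster and calibration
    generators make every stage testable without trained neural backends.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    withr,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    cluster,
    nnet,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
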