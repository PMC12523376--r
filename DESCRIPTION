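Package: tnv2
Title: Lightweight Pooling-Attention Convolutional Networks for
    Plantar-Pressure Image Classification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Implements the TurkerNeXtV2 lightweight convolutional
    architecture for biological image classification: a ConvNeXt-style
    patchify stem, TNV2 blocks built from parameter-free pooling-based
    attention and grouped inverted bottlenecks, hybrid pooled/strided
    downsampling, and a global-average-pooling classification head.
    Provides a from-scratch training engine (SGD with momentum, L2 decay,
    best-validation checkpointing), the full confusion-matrix metric suite
    (per-class and macro precision/recall/F1, specificity, geometric mean,
    balanced accuracy, binomial accuracy inference, precision-recall
    curves), Grad-CAM saliency from the last convolutional stage, a
    class-foldered image reader, and a synthetic plantar-pressure image
    generator so the whole stack is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    jsonlite,
    stats,
    grDevices,
    graphics,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
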