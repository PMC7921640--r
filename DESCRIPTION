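Package: hierstack
Title: Hierarchical Classification with Hierarchy Transfer Learning and
    Stacked Multimodal Ensembles for Small Image Datasets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A two-step training framework for image-based disease
    detection and subtype classification when labelled data are scarce.
    A low-level model first separates normal from diseased cases; the
    subtype model is then initialised from the low-level model's learned
    features (hierarchy transfer learning) and trained on diseased cases
    only.  Per-modality confidence vectors are combined by a linear
    support-vector metamodel, and models trained on different input-image
    modalities are fused by a stacking ensemble.  Includes a seeded
    multi-modal synthetic image generator emulating optic-disc imaging
    with one deliberately weak modality, a compact seeded convolutional
    network engine with transfer-learning hooks, chance-corrected
    evaluation statistics (Cohen's kappa, balanced accuracy, one-vs-rest
    ROC/AUC), and orchestration for strategy-comparison and
    learning-curve experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    EBImage,
    jsonlite,
    png,
    stats,
    utils,
    grDevices,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
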