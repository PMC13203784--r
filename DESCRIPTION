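Package: lesionseg
Title: Transformer-Enhanced Hybrid U-Net for Binary Breast-Lesion Segmentation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a hybrid residual-CNN/Transformer U-Net for binary
    segmentation of breast lesions in 2-D medical images (ultrasound,
    histology, mammography, MRI), together with its combined binary
    cross-entropy plus Dice training objective, training automation
    (Adam, plateau learning-rate schedule, early stopping, gradient
    clipping, best-checkpoint selection), warm-start sequential transfer
    learning across datasets, an evaluation battery (Dice, IoU, accuracy,
    per-class precision/recall/F1, ROC-AUC, percentile-bootstrap
    confidence intervals), patient-level data splitting with augmentation,
    and a synthetic phantom generator that emulates the statistical
    character of the four imaging modalities so the whole pipeline is
    exercisable without clinical data. All network layers, including the
    multi-head self-attention bottleneck and full backpropagation, are
    implemented on top of BLAS matrix operations.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
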