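Package: farrowdet
Title: Noisy-Student Detection Pipeline for Newborn Piglets in Farrowing Pens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Semi-supervised ("noisy student") object-detection pipeline for
    monitoring farrowing pens. A teacher detector trained on full-pen images
    locates the sow's head and rear, from which a restricted circular birth
    region behind the sow is derived; the region is cropped and rescaled, the
    class space is reduced to tail and piglet, and confidence-filtered teacher
    detections become pseudo-labels for training a student detector under
    augmentation noise (flips, mixup, dropout). Includes a seeded synthetic
    farrowing-scene generator with pixel-accurate ground truth, YOLO and
    LabelMe annotation I/O, a CPU-scale trainable reference detector, and
    region-restricted Recall/Precision/F1 evaluation with micro-averaged
    pooled metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    grDevices,
    graphics,
    jsonlite,
    png,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
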