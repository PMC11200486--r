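Package: oculoseg
Title: Multi-Class Ocular Segmentation Losses, Boundary Metrics and
    Ptosis Indicators for Ocular Myasthenia Gravis Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for five-class eye segmentation masks (pupil, iris,
    sclera, lacrimal caruncle, skin): palette PNG mask input/output,
    segmentation loss functions (cross-entropy, weighted cross-entropy,
    soft IoU, Dice, and a boundary-band soft IoU loss) with a scheduled
    hybrid combination, boundary-aware evaluation metrics (MIOU, MDice,
    MPrecision, MRecall, MF1, MBIOU), geometric ocular indicators
    (palpebral fissure height, clock-point ptosis grading, directional
    scleral-area proportion) via direct least-squares ellipse fitting,
    a rule-based ocular myasthenia gravis screening decision, and a
    parametric synthetic eye-mask generator with analytically known
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    png,
    jsonlite,
    yaml,
    EBImage,
    stats
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
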