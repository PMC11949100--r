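Package: pterygrade
Title: Automated Pterygium Severity Assessment from Anterior-Segment
    Segmentation Masks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies pterygium invasion of the cornea from 3-class
    anterior-segment label masks (pterygium / pupil / cornea). Reconstructs
    the full corneal and pupillary circles from incomplete contours by
    iteratively reweighted least squares with Huber or Tukey (biweight)
    M-estimation weights, measures the invasion area ratio and invasion
    depth ratio, converts depth to millimetres via a reference corneal
    diameter, and assigns the three-level clinical severity grade
    (<= 3 mm invasion; > 3 mm but pupil spared; pupil covered).  Ships a
    synthetic anterior-segment phantom generator with analytically known
    invasion geometry, segmentation-quality and grading-agreement metrics
    (IoU, Dice, precision, recall, accuracy, weighted F1, Cohen's kappa,
    reference-diameter sweep), and a compact hybrid CNN-transformer
    encoder-decoder segmentation network with a channel-and-shape
    attention module on the skip connections, trainable at smoke scale on
    phantoms.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    png,
    stats,
    utils,
    yaml
Suggests:
    caret,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
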