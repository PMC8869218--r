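Package: colonyforge
Title: Few-Shot Dataset Construction and Evaluation for Bacterial Colony
    Counting Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building few-shot object-detection datasets from
    bacterial colony plate photographs and for evaluating colony counters.
    Implements annotation-preserving data augmentation by random target
    coverage (erasing randomly chosen colonies with a locally estimated
    background colour and pruning the corresponding bounding boxes),
    quarter-cutting and lossless rotation of images together with their
    box annotations, YOLO-darknet label input/output and dataset assembly
    with train/validation splitting, two threshold-segmentation baseline
    counters, counting metrics (average accuracy, true positive rate,
    false negative rate), per-colony size statistics, and a synthetic
    plate-image generator with exact ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    grDevices,
    methods,
    png,
    stats,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
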