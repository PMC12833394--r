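Package: fracdet
Title: Adaptive-Anchoring Two-Stage Detection for Long-Bone Fracture
    Radiographs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for computationally efficient two-stage object detection
    on long-bone radiographs. Implements adaptive anchoring, which restricts
    region-proposal-network anchor generation to the central image region
    where diaphyseal fractures occur, together with the surrounding pipeline:
    feature-pyramid anchor-budget accounting, radiograph brightness
    normalization, bounding-box-aware augmentation, stratified splitting and
    class-imbalance weighting, a deterministic rule engine mapping fracture
    descriptors to four orthopedic treatment classes, Grad-CAM saliency maps
    with a label/image randomization sanity check, detection metrics
    (precision, recall, F1, average precision, bootstrap confidence
    intervals), and a synthetic long-bone phantom generator so the whole
    pipeline is testable at desk scale without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    png,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
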