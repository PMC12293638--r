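Package: periocrop
Title: Oriented Bounding-Box Detection Tools for Periocular Region Cropping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for working with rotated (oriented) bounding boxes around the
    periocular region in full-face ocular-alignment photographs. Implements exact
    skew intersection-over-union via polygon intersection and fan triangulation,
    the ProbIoU regression loss built from Gaussian box surrogates and the
    Bhattacharyya distance, the distribution focal loss over discretized box
    offsets, rotated-box detection evaluation (precision, recall, mAP50, mAP95),
    letterbox and mosaic data augmentation, a head-tilt-correcting deskew crop
    with user-adjustable margins, and the clinical upload quality-assurance gate
    (resolution, shooting-distance and detection-confidence checks). A procedural
    generator of face-like scenes with exact ground-truth eye-region boxes and a
    classical blob-pairing baseline detector let the full detect, QA, crop and
    evaluate pipeline run end to end without any trained network.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    png,
    xml2,
    yaml,
    jsonlite,
    Rcpp,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pracma
Config/testthat/edition: 3
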