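Package: slns
Title: Self-Learning Network-Based Segmentation of Brain MR Slices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Locates tumor-like regions in 2-D brain magnetic resonance
    slices with the two-phase HARIS heuristic (region-count selection by a
    weighted fitness of between-class variance and intraclass correlation,
    then intensity-driven region assembly around local-best feature pixels),
    preceded by an adaptive bilateral filter with a contra-harmonic
    brightness target and fuzzy-entropy thresholding, and followed by
    structural-similarity (ASSI) or fuzzy-membership pixel classification.
    A self-learning experience store warm-starts later runs from earlier
    outcomes. Ships a deterministic synthetic brain-phantom generator with
    exact ground truth, segmentation evaluation metrics (sensitivity,
    specificity, accuracy, Jaccard similarity, Matthews correlation, tumor
    burden), PNG/NIfTI image input and output, and a small command-line
    front end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    png,
    RNifti,
    jsonlite,
    yaml,
    withr,
    EBImage,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
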