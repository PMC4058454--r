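Package: hmacell
Title: Hierarchical Mergence Detection of Cells in Phase-Contrast Microscopy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects individual cells in phase-contrast microscopy images by
    hierarchical mergence of homogeneous patches. A permissive maximum region
    of interest is built from multi-scale Canny edge maps and binary
    morphology; iterated Gaussian blurring and grayscale morphological
    reconstruction produce reference images; each connected region of the
    mask is partitioned independently by exhaustive multilevel Otsu
    thresholding; informative layers (including interior holes of bright
    boundary sections) are extracted recursively and merged into a raw
    segmentation; adherent patches are split by marker-controlled watershed
    and non-cell patches are removed by a support vector machine trained on
    morphological, intensity and local-binary-pattern features. Includes a
    synthetic phase-contrast scene generator with per-cell ground truth and
    a cell-level matching evaluator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    Matrix,
    Rcpp,
    e1071,
    jsonlite,
    grDevices,
    png,
    stats,
    tiff,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
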