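Package: dexafod
Title: Unsupervised Foreign Object Detection in Dual-Energy X-ray Projections
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Detection of low-contrast foreign objects (such as bone fragments
    in chicken fillets) in dual-energy X-ray absorptiometry (DEXA) projections.
    Implements a polychromatic spectral forward model, a data-driven quadratic
    thickness-correction of the dual-energy quotient image with bin-wise noise
    normalization, two-phase Chan-Vese active-contour segmentation, and
    cluster-size-based detection with a binary defected/normal verdict.
    Includes a synthetic phantom generator producing noisy dual-energy
    projection pairs with ground-truth defect masks, plus pixel- and
    sample-level evaluation (F1 score, confusion matrices, penalty-weight
    sweeps).
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
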