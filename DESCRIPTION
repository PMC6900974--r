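Package: stacksr
Title: Automated Multicolor Cell Detection and Confetti Clonal Composition Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for multicolor (Brainbow2.1/Confetti) fluorescence
    microscopy and flow-style analysis of clonally marked hematopoietic
    cells. Implements a stochastic two-allele Cre recombination simulator
    with an optional retroviral Cre-GFP marker, a synthetic multichannel
    confocal field renderer with per-cell ground truth, the "Stacks"
    segmentation pipeline (contrast stretch, composite thresholding just
    above the background peak, erosion-based separation of touching cells
    with geodesic constrained expansion, object filtering, per-cell mean
    intensity measurement), data-driven per-channel positivity thresholds,
    ten-class XFP color classification with exclusion-gating semantics, and
    per-group clonal composition reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    tiff,
    png,
    yaml,
    jsonlite,
    withr,
    Rcpp,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
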