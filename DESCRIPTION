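Package: enameloct
Title: Automated Tooth Enamel Thickness Measurement from Dental OCT Volumes
Version: 0.1.0
Authors@R:
    person("OCT", "Imaging Lab", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Fully automatic quantification of tooth enamel thickness from
    optical coherence tomography (OCT) B-scan volumes across the stages of
    orthodontic treatment with fixed braces. Implements 3-D median
    pre-filtering, Otsu-based detection of the outer tooth surface,
    per-A-scan histogram thresholding of the enamel/dentine transition,
    morphological cleaning with largest-component selection, cubic-polynomial
    smoothing of the inner enamel boundary, en-face (C-scan) projection
    registration by exhaustive translation-and-zoom search minimising a sum
    of absolute differences, greedy active-contour delineation of the tooth
    region of interest, and per-stage thickness statistics with pairwise
    stage-difference matrices. A synthetic phantom generator with known
    ground truth makes every stage testable without proprietary scanner data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
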