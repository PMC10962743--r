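Package: weakbox3d
Title: Weak 3D Box Labels and Lesion-Level Detection Evaluation for CT
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for training and evaluating lesion detectors on CT volumes
    when only single-slice 2D bounding-box annotations are available. Extends
    RECIST-style 2D boxes into weak 3D box labels, merges them with a
    body-region mask into a multi-class training label map, and implements a
    complete lesion-level detection evaluation protocol: 3D connected-component
    extraction, prediction-size thresholding (including percentile-based
    threshold selection), overlap matching, and precision/recall aggregation at
    dataset and patient level. A seeded synthetic CT phantom generator with
    controllable prediction degradation makes every stage testable end to end
    without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
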