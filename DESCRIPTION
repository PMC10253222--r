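Package: craniomark
Title: Multi-Phased Coarse-to-Fine Regression of Craniofacial Landmarks in CT Slice Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts three-dimensional coordinate values of 16 craniofacial bony
    landmarks from series of axial CT slices using a three-phase coarse-to-fine
    scheme: a whole-volume 3D residual regression network produces a rough
    estimate, and two successive per-landmark networks re-predict the position
    from progressively smaller full-resolution crops centred on the previous
    estimate.  Includes a minimal DICOM slice reader/writer, the crop-window
    algebra with exact local/global coordinate remapping, shift-grid crop
    augmentation, the 3D residual network regressor with training code, a
    synthetic skull-phantom generator with exact landmark ground truth, and
    per-axis / 3D Euclidean error analysis with Conover-Iman post-hoc
    phase comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    yaml,
    jsonlite,
    igraph,
    optparse
Config/testthat/edition: 3
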