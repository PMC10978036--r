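Package: tomoprior
Title: Sparse-View CT Reconstruction with a Learned CNN Penalty
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Iterative reconstruction of 2-D parallel-beam computed tomography
    from under-sampled (few-view) sinograms. A small convolutional classifier is
    trained to distinguish full-view from few-view filtered-backprojection
    reconstructions; stripping its output sigmoid turns it into a real-valued
    image-quality score that is used, together with a data-fidelity term and a
    total-variation penalty, in a steepest-descent variational objective.
    Includes a parallel-beam projector with an exact adjoint, filtered
    backprojection, an anatomically structured random-phantom generator for
    building labelled training corpora, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    tiff,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
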