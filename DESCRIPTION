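Package: cmpens
Title: Ensemble Averaging of Pixelwise Class-Membership Probabilities for Cell Segmentation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and evaluating ensembles of pixelwise
    cell/no-cell probability predictors in micrograph segmentation. Per-pixel
    class-membership probabilities (CMPs) from many independently trained patch
    classifiers are fused by four aggregation rules (mean, median, majority
    vote, and the location parameter of a Levy alpha-stable distribution fit
    via its characteristic function) and the binarized consensus is scored
    against ground truth with binary and continuous accuracy and Dice metrics.
    Includes the ten-layer patch classifier the ensembles are built from, with
    L1-norm convolutional filter pruning, the eight ensemble recipes (random
    seeds, pruning schedules, training-size ladders), an ensemble-size
    saturation sweep, and a synthetic micrograph generator so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    tiff,
    png,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
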