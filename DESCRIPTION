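Package: periometry
Title: Automated Periocular Anthropometry from Calibrated Facial Photographs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to automate periocular measurements from frontal facial
    photographs. Detects ten periocular landmarks (pupillary centres, upper
    and lower eyelid margin midpoints, medial and lateral canthi) with a
    trainable Gaussian-heatmap regression network, converts pixels to
    millimetres using a green circular fiducial sticker of known diameter,
    and computes seven clinical metrics: marginal reflex distances 1 and 2,
    palpebral fissure height, horizontal palpebral aperture, and inner and
    outer intercanthal and interpupillary distances. Includes a synthetic
    scene generator with analytic ground truth for training and validation,
    landmark-accuracy evaluation (normalised mean error and failure rate),
    and human-versus-automated agreement statistics (mean absolute error,
    Bland-Altman limits of agreement with confidence intervals, and the
    single-measures absolute-agreement intraclass correlation coefficient).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    grDevices,
    graphics,
    jsonlite,
    png,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
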