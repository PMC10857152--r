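Package: phantomreg
Title: Registration Accuracy Evaluation for Mixed-Reality Neuronavigation
    with Synthetic Head Phantoms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for evaluating the spatial accuracy of image-guided
    (mixed-reality) neuronavigation on head phantoms. Implements the
    position-dependent coordinate-frame transform chain between the
    reference image space and a left-handed virtual display space,
    least-squares rigid landmark registration, landmark-based error
    metrics (fiducial localization error, target registration error,
    fiducial registration error, Frobenius norm of the misregistration),
    lesion-based overlap metrics (Dice similarity coefficient,
    95th-percentile Hausdorff distance) with lesion characteristics
    (volume, depth below the skin, distance from the image origin), and
    the nonparametric cohort statistics used to compare surgical
    positions. A synthetic head-phantom generator reproduces the
    statistical structure of a 19-case phantom cohort so the whole
    analysis runs end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    minpack.lm,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
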