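Package: wellmotion
Title: Label-Free Viability Profiling from Bright-Field Time-Lapse Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantifies leukemia-cell viability in 384-well co-culture drug
    screens from bright-field time-lapse image stacks, without viability dyes.
    Live non-adherent cells show small membrane movements between consecutive
    frames while dead cells are static; a trailing running-maximum projection
    followed by frame subtraction, Gaussian smoothing and thresholding turns
    that motion into a per-well live pixel area trace. The package provides
    drift registration, the two-step normalization (to the well's own 3-h
    baseline, then to vehicle-control wells), assay quality control, LD50 and
    AUC dose-response summaries with censoring, cross-sample screen analytics,
    and a seeded synthetic time-lapse simulator with per-cell ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    readr,
    jsonlite,
    yaml,
    tiff,
    png,
    EBImage,
    pracma,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
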