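Package: switchscope
Title: Single-Cell Analysis of Stochastic White-Opaque Switching
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for quantifying rare, stochastic switching between
    heritable transcriptional cell states from time-lapse microfluidic
    microscopy and flow cytometry. Provides a ground-truthed synthetic-data
    generator for trap movies, cell pedigrees and flow plates; frame
    registration, morphological cell segmentation and top-pixel
    fluorescence quantification; pedigree-aware classification of
    switching events and their kinetics; Poisson zero-class null models
    with Monte-Carlo goodness-of-fit tests for clustered events; and
    robust four-parameter log-logistic (Hill) fitting of single-cell
    dose-response data to quantify ultrasensitive autoregulation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    rlang,
    EBImage,
    tiff,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
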