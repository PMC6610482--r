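Package: atrialmap
Title: Optical Mapping Analysis and Synthetic Voltage-Dye Movies for
    Atrial hiPSC-CM Monolayers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for cardiac optical mapping of atrial-like
    hiPSC-derived cardiomyocyte monolayers: signal conditioning of
    voltage-sensitive dye movies (background masking, delta-F/F, spatial
    binning, inversion, FFT low-pass, polynomial drift correction),
    optical action potential metrics (cycle length, APD, Bazett-corrected
    APD, maximal upstroke slope, alternans), activation mapping, and
    classification of conduction outcomes across pacing-frequency sweeps
    with success-rate tables and Fisher's exact comparisons. Includes a
    synthetic-data module that simulates two-dimensional excitable-media
    electrical activity on narrow-isthmus and uniform plate geometries,
    with optional fibroblast heterogeneity, and renders realistic
    negative-polarity fluorescence movies so the whole pipeline can be
    exercised without wet-lab recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
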