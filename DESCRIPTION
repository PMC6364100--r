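Package: phenolscreen
Title: Screening and Surrogate-Standard Quantification of Plant Phenols
    by Miniature Single-Quadrupole LC-MS
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates and analyses unit-resolution dual-polarity LC-MS
    runs for the screening and measurement of phenols (bibenzyls,
    phenanthrenes, flavones, coumarin) in Dendrobium chrysotoxum.
    Implements chromatographic peak detection and integration,
    adduct-fingerprint classification of unknown peaks into phenol
    families, surrogate-standard quantification, signal-to-noise based
    LOD/LOQ estimation, spike-recovery method validation, and content
    reporting with below-LOQ handling.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    mzR,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
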