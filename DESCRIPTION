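Package: csiatp
Title: Trophic Position Estimation from Amino Acid Nitrogen Isotopes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates consumer trophic position from compound-specific
    nitrogen isotope measurements of amino acids (CSIA-AA). Implements four
    published trophic-position equations built on the glutamic-acid (Glx) /
    phenylalanine (Phe) delta-15N pair, including single- and dual-TDF
    (trophic discrimination factor) frameworks, with first-order Taylor-series
    propagation of measurement and parameter uncertainty and a Monte-Carlo
    cross-check. Ships tidy readers for long- and wide-format amino-acid
    delta-15N tables, diet-weighted stomach-content trophic positions, a
    forward food-web fractionation simulator for validating the estimators
    (including scenarios with non-negligible trophic Phe enrichment), and a
    compiled multi-species cetacean dataset.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
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
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
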