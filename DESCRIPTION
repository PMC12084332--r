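Package: gsl4d
Title: 4D Glycosphingolipidomics: Annotation and Partition-Corrected
    Semi-Quantification of Serum Glycosphingolipids
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computational toolkit for four-dimensional (m/z, retention time,
    collisional cross section, MS/MS) glycosphingolipidomics of two-fraction
    serum extracts. Parses lipid shorthand nomenclature for gangliosides,
    neolacto-series, neutral glycosphingolipids and sulfatides; computes
    elemental compositions, monoisotopic masses and ion m/z; generates
    in-silico glycosidic and ceramide fragment ions with the diagnostic-ion
    screening rules used for ganglioside identification; matches features
    against 4D reference libraries with tolerance windows and cosine spectral
    scoring; performs internal-standard partition-corrected semi-quantification
    (average-partition and per-sample strategies, plus outlier-corrected
    combination); fits calibration curves with LLOD/LLOQ estimation; and
    provides Mann-Whitney differential-abundance tables with
    Benjamini-Hochberg correction. Includes seeded synthetic-data generators
    for two-fraction cohorts, diagnostic-ion spectra and dilution series.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    stringr,
    ggplot2,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
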