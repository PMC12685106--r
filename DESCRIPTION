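Package: desimsi
Title: DESI Mass Spectrometry Imaging Lipidomics Classification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: An end-to-end analysis pipeline for desorption electrospray
    ionization mass spectrometry imaging (DESI-MSI) lipidomics of
    two-class tissue cohorts: imzML import/export, region-of-interest
    spectrum averaging, ppm-constrained peak matching, probabilistic
    quotient normalization, recursive maximum margin criterion
    discriminant analysis with leave-one-patient-out cross-validation,
    univariate feature statistics with false discovery rate control,
    lipid annotation against an accurate-mass reference table with
    carbon-13 isotopologue handling, per-protein logistic regression for
    reverse phase protein array data, and cosine-distance lipid-protein
    integration. A synthetic cohort generator with planted effects makes
    every stage testable without raw data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    xml2,
    jsonlite,
    ape,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
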