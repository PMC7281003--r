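Package: herdnmr
Title: Fixed-Effect Correction and Chemometrics for Multi-Herd 1H NMR
    Serum Metabolomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing large, multi-farm 1D 1H NMR serum
    spectral datasets from early-lactation dairy cattle. Provides a
    synthetic multi-herd cohort generator with configurable fixed-effect
    structure, a spectral preprocessing chain (region excision,
    correlation optimised warping, total-area normalisation, asymmetric
    weighted least squares baseline removal, mean centering), per-shift
    linear-model residualisation of spectra for herd, parity and
    week-of-lactation effects, principal component comparisons,
    conditional Wald F inference, ANOVA-simultaneous component analysis
    with permutation testing, and OPLS regression of serum
    beta-hydroxybutyrate with venetian-blinds and leave-one-farm-out
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    Matrix,
    data.table,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
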