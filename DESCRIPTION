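Package: serslda
Title: Classification of SERS Spectra of Glycoprotein Isoforms by Linear
    Discriminant Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidy pipeline for discriminating surface-enhanced Raman
    scattering (SERS) spectra of the same protein produced by different cell
    types. Provides a seeded synthetic-spectrum generator with Lorentzian
    vibrational bands, fluorescence-like baseline drift and cosmic-ray
    spikes; spectral preprocessing (range selection, rubber-band baseline
    correction, robust per-wavenumber outlier elimination, per-spectrum
    standardization and Savitzky-Golay smoothing); linear discriminant
    analysis built explicitly from within- and between-class scatter
    matrices with ridge shrinkage; nearest-centroid classification with
    per-class precision, sensitivity and F score; and a feature-importance
    workflow that quantile-filters discriminant weights, measures accuracy
    as a function of the number of top-ranked wavenumbers, and groups the
    selected wavenumbers into contiguous spectral intervals matched against
    a packaged vibrational band-assignment table.
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
    jsonlite,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
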