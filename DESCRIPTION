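Package: shofactor
Title: Factor Analysis Linking Herbal Formula Composition and MS Fingerprints to the Sho Diagnostic Axis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Chemometric pipeline relating Kampo herbal formula composition
    matrices and direct-infusion mass-spectrometry fingerprints to the Sho
    constitutional diagnosis (Deficiency/Middle/Excess). Provides
    composition-table I/O, fixed-width m/z spectral binning, principal
    component analysis with variance proportions, factor loadings and
    t-test selection of class-discriminating axes, single-response NIPALS
    partial least squares with cross-validated Q-squared component
    selection, sign-rule classification with recognition rates and
    coefficient tables, plus a synthetic-data generator with planted class
    structure for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    optparse,
    readxl,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
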