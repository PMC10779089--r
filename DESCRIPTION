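Package: icdbind
Title: Induced Circular Dichroism Analysis of Cyclodextrin Host-Guest Complexes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterising 1:1 drug-cyclodextrin inclusion complexes
    from induced circular dichroism (ICD) and UV titrations. Reads and converts
    plain-text CD/UV spectra, applies FFT low-pass smoothing, fits association
    constants from single-wavelength saturation curves and by global
    multi-wavelength variable projection, models the two-state UV mixture
    (mole-fraction weighted free and complexed guest), derives the cyclodextrin
    cavity frame from 3-D coordinates, and predicts the ICD band sign from the
    transition-dipole orientation via the Kodaka-Harata rules. Includes a
    synthetic-data generator for titration series and toy cyclodextrin
    geometries so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    purrr,
    tidyr,
    rlang,
    ggplot2,
    jsonlite,
    generics,
    bio3d,
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
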