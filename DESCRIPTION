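Package: ramankin
Title: Low-Frequency Raman Spectral Processing and Solid-State Dehydration Kinetics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for time-resolved low-frequency Raman spectroscopy of
    solid-state transformations, with a focus on hydrate dehydration in
    pharmaceutical powders. Implements Bose-factor reduced intensity and
    Raman susceptibility transforms, decomposition of the low-frequency
    spectrum into quasi-elastic scattering, a lognormal vibrational density
    of states and phonon peaks, extraction of transformation-rate curves
    rho(t) from spectral series by two-endmember unmixing or water-band-area
    tracking, and fitting and selection among classical solid-state kinetic
    models (Avrami, Jander and peers). Includes a fully seeded synthetic
    spectral-series generator so every pipeline stage is testable against
    known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    readr,
    generics,
    jsonlite,
    yaml,
    minpack.lm,
    pracma,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
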