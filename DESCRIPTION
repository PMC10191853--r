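Package: flashkin
Title: Flash-Resolved Kinetics of Photosynthetic Oxygen Evolution
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis chain for time-resolved spectro-kinetic studies of
    photosystem II oxygen evolution. Provides Kok S-state bookkeeping across a
    laser-flash train and least-squares deconvolution of flash-indexed data
    into pure S-state-transition datasets; global multiexponential fitting
    with shared time constants by variable projection, yielding
    decay-associated spectra (DAS); acceptor-side and heat-artifact spectral
    corrections; Arrhenius regression and Eyring transition-state
    decomposition of activation free energies into enthalpic and entropic
    terms; a one-dimensional reaction-diffusion forward model of flash-induced
    oxygen polarography with first-order high-pass filtering; and a
    ground-truth synthetic-data generator so the whole pipeline is testable
    without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
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
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
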