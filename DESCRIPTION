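Package: stmnoise
Title: Exponential Spectro-Temporal Modulated Noise by Bessel Sideband Synthesis
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Synthesis of noise with exponential (log-amplitude sinusoidal)
    spectro-temporal modulation in the frequency domain. Each carrier tone of a
    multi-tone noise is expanded into a base tone plus sidebands whose
    amplitudes are values of the modified Bessel function of the first kind, so
    that an arbitrarily deep ripple stimulus is rendered with a single inverse
    DFT. Includes an explicit time-domain reference renderer, truncation-error
    (energy-deficiency) diagnostics for choosing the sideband extent,
    band-shaped random-carrier noise design, spectral-envelope validation
    metrics (normalized fourth moment, crest factor, spectrogram power ratios),
    WAV/CSV export and a command-line interface.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    optparse,
    signal,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
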