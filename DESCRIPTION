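Package: sersdemux
Title: Demultiplexing and Reliability Assessment of Multiplexed SERS Nanoparticle Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for unmixing Raman spectra of surface-enhanced Raman
    scattering (SERS) coded nanoparticle mixtures by direct classical least
    squares (DCLS) with a third-order polynomial baseline, and for judging
    whether a single measurement is trustworthy. The package computes the
    relative fitting error (RFE) and the spectral reliability index (SRI),
    calibrates error-versus-SRI curves by Monte-Carlo simulation (Gaussian
    error model for single flavors, gamma model for composite errors of
    mixtures), extracts confidence-bounded error values such as e80, builds
    minimum-SRI lookup tables across mixture ratios, and applies an
    accept/reject decision workflow to raw measurements. A synthetic spectral
    library generator (Lorentzian multi-peak flavors over a smooth broadband
    background) supports simulation studies and calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    fitdistrplus
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
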