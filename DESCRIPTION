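Package: tfbgdemod
Title: Machine-Learning Demodulation of Plasmonic Fiber-Grating Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Signal processing and calibration for gold-coated tilted
    fiber Bragg grating (TFBG) surface-plasmon-resonance refractometers.
    Provides Jones-calculus handling of polarization-resolved insertion-loss
    spectra, a band-pass envelope demodulation in the generalized frequency
    domain that tracks the plasmon notch to sub-resolution precision, a
    grouped cross-validated linear calibration mapping envelope-minimum
    shifts to refractive-index changes, sensorgram analysis (dispersion,
    detection limit, step reports), and a physics-based synthetic spectrum
    simulator for benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
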