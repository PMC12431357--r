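Package: uwbvitals
Title: Vital-Sign Extraction from Airborne Ultra-Wideband Bio-Radar
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for recovering respiration and heartbeat from
    impulse-radio ultra-wideband (IR-UWB) radar mounted on a moving
    (hovering) platform. Implements range-migration compensation by
    envelope alignment and phase compensation, moving-average DC drift
    removal, energy-based target localization, multi-channel slow-time
    extraction with baseline removal, JADE blind source separation
    (whitening with noise-variance correction, fourth-order cumulant
    matrices, joint approximate diagonalization), and heartbeat recovery
    by band-pass filtering and feedback-notch suppression of respiratory
    harmonics. A physics-based echo simulator generates radar cubes with
    sinusoidal chest displacement, platform motion, static reflectors and
    band-limited Gaussian vegetation clutter, so the whole pipeline is
    testable without radar hardware.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    Matrix,
    jsonlite,
    yaml,
    nortest,
    minpack.lm,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
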