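Package: pwdoppler
Title: Digital Multigate Pulsed-Wave Doppler Processing for High Frequency Ultrasound
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A fully digital multigate pulsed-wave (PW) Doppler processing chain
    for high frequency ultrasound RF data: Hilbert-transform quadrature
    demodulation (analytic-signal construction after zero-phase band-pass
    filtering), multigate slow-time extraction, Hamming-windowed complex-FFT
    sonogram generation with log compression, angle-corrected spectral velocity
    estimation with intrinsic spectral-broadening correction, and trapezoidal
    integration of wall velocities to displacement traces. Includes a
    physics-based RF echo simulator (moving reflector, parabolic vessel flow,
    oscillating walls) with known ground truth, a versioned RF container
    format, and a command-line interface chaining the pipeline stages.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    signal,
    stats,
    utils,
    grDevices,
    graphics,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
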