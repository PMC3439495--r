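Package: lcdtempo
Title: Temporal Photometric Characterization of Liquid Crystal Displays
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for analyzing time-resolved luminance recordings of
    liquid crystal displays (LCDs) for vision-science applications.
    Decomposes transition recordings into the liquid-crystal transition
    component and the backlight modulation by the division method with
    dynamical filtering, estimates ISO 9241-style 10--90 percent response
    times and overshoot-extended response times, detects overdrive (DCC)
    artifacts such as luminance overshoot, stepping and pre-tilt onset
    advance, characterizes backlight pulse-width modulation and frame
    response from periodograms, and predicts visible motion blur in just
    noticeable differences from moving-edge temporal profiles.  Includes a
    synthetic LCD signal generator with ground truth for validating every
    estimator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
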