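Package: valvometry
Title: Valvometric Analysis of Bivalve Gaping Behavior
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analyzing Hall-effect valvometer records of bivalve
    (giant clam) shell gaping behavior together with co-located environmental
    sensor series. Reads raw tab-delimited voltage logs and environmental CSV
    exports, screens for sensor faults (voltage rails, loss of diurnal
    signal), normalizes voltages to daily z-scores and percent closure,
    delineates rapid valve-closure ("valve clapping") events with a
    prominence-based peak detector, relates daily closure frequency to
    environmental covariates with additive spline models and lead/lag
    cross-correlation, and characterizes circadian and ultradian rhythmicity
    with a Morlet continuous wavelet transform, band reconstruction, and
    wavelet coherence with phase. A seeded simulator generates synthetic
    light, water chemistry, plankton, clam behavior, and sensor transduction
    with known ground truth so every pipeline stage can be validated end to
    end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    mgcv,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
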