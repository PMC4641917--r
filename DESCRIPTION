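Package: fnirsim
Title: Digital Twin of a Modular Continuous-Wave fNIRS Instrument and
    Single-Trial BCI Analysis Pipeline
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the full signal path of a modular continuous-wave
    functional near-infrared spectroscopy (fNIRS) instrument: dual-wavelength
    (750/850 nm) LED emitters with square-wave lock-in modulation, photodetection
    with shot and dark noise, programmable gain, square-wave lock-in demodulation
    with phase-shift attenuation, time-division multiplexed channel scheduling
    driven by a 4-bit control interface, and 16-bit ADC quantization. Re-derives
    the instrument's bench characterization figures (noise-equivalent power,
    signal-to-noise distance, saturation power, dynamic range, drift) from
    measured quantities, generates synthetic mental-arithmetic experiments with
    ground-truth hemodynamics via the modified Beer-Lambert law, and implements a
    single-trial brain-computer-interface pipeline (detrending, moving-average
    subtraction, elliptic low-pass filtering, trial extraction, slope features,
    LDA with stratified cross-validation and significance testing against chance).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    MASS,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
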