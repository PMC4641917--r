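# fnirsim

A digital twin of a modular, lock-in-based continuous-wave fNIRS
(functional near-infrared spectroscopy) instrument and of the
single-trial mental-arithmetic BCI analysis used to validate such
instruments.

CW-fNIRS estimates changes in oxygenated and deoxygenated hemoglobin
(ΔHbO, ΔHbR, in µmol/L) from back-scattered near-infrared light at two
wavelengths (750/850 nm) via the modified Beer–Lambert law,

    ΔOD(λ) = (ε_λ,HbO·ΔHbO + ε_λ,HbR·ΔHbR) · d · DPF,

with source–detector distance *d* and differential pathlength factor
DPF. `fnirsim` is aimed at instrument developers and BCI methodologists
who want to exercise an fNIRS acquisition and analysis chain against
ground truth. It provides:

* **Instrument simulation** — LED drive with square-wave modulation at
  3.125 kHz, photodetection with shot/dark noise, programmable gain
  (0.6875–88 plus a fixed 5.1 post-filter gain), square-wave lock-in
  demodulation with phase-shift attenuation *A* = cos(2πΔt/T),
  time-division-multiplexed channel scheduling driven by a 4-bit
  control-line state machine, and 16-bit ADC quantization
  (`simulate_acquisition()`, `lock_in_demodulate()`, `digitize()`,
  `build_tdm_schedule()`, `encode_control()`/`decode_control()`).
* **Bench characterization** — noise-equivalent power
  NEP = (μ_d + σ_d)/(R·G), signal-to-noise distance, saturation power,
  dynamic range, fNIRS signal margin and least-squares drift estimation
  (`characterize()` and the individual functions behind it).
* **Synthetic physiology** — block-design mental-arithmetic sessions
  (30 × 10 s trials, 25–30 s pauses, a long rest after trial 15) with a
  double-gamma hemodynamic response, cardiac pulse, slow systemic
  oscillation, drift and measurement noise, all seeded and reproducible
  (`generate_protocol()`, `build_scene()`).
* **Analysis pipeline** — MBLL inversion, 300 s windowed detrending,
  ±30 s moving-average subtraction, order-6 elliptic low-pass at 0.5 Hz,
  trial extraction, per-trial least-squares slope features, and LDA
  under stratified 10-fold cross-validation with a one-sided t-test
  against chance (`run_bci_pipeline()`).

The instrument's native ASCII CSV packet format is read and written by
`write_packets()`/`parse_packets()`; series export with probe metadata
(wavelengths, 35 mm source–detector separation, Fp1/Fp2/AFz labels) goes
through `export_series_csv()`.

## Worked example

```r
library(fnirsim)

## Bench characterization from the instrument's measured inputs
characterize()
#> Instrument characterization
#>   lock-in phase-shift attenuation A: 0.875
#>   750 nm: NEP 0.851 nWrms (formula) / 2.27 nWpp (measured) | SNR distance 128.0 dB | saturation 1.296 uWpp | dynamic range 55.13 dB | fNIRS margin 28.0 dB
#>   850 nm: NEP 0.780 nWrms (formula) / 2.21 nWpp (measured) | SNR distance 127.7 dB | saturation 1.188 uWpp | dynamic range 54.61 dB | fNIRS margin 27.7 dB

## One synthetic session: protocol -> physiology -> TDM acquisition -> analysis
protocol  <- generate_protocol(n_trials = 30, seed = 1)
scene     <- build_scene(protocol, seed = 1)
recording <- simulate_acquisition(scene, seed = 1001)
result    <- run_bci_pipeline(recording, protocol)
result$cv
#> LDA 10-fold cross-validation on 60 trials
#>   mean accuracy 0.567 (folds 0.33 0.33 0.50 0.50 0.33 0.50 0.67 0.83 0.83 0.83)
#>   one-sided t-test vs chance 0.5: p = 0.1717
```

The attenuation line says the lock-in loses 12.5 % of its gain to the
measured 25.7 µs phase mismatch; the 128/127.7 dB figures are the
distances between the LED power reaching the tissue and the optical
power equivalent to the detection noise floor; saturation and dynamic
range bound the usable input range at minimum gain; and the 28 dB margin
is what remains for the physiological signal after ~60 dB tissue loss
and the fNIRS component being ~1 % of the measured intensity.

A single simulated session classifies task vs. pause well above chance
in most seeds but not all — as with real subjects. Aggregating sessions:

```r
accs <- vapply(1:10, function(s) {
  protocol <- generate_protocol(30, seed = s)
  scene    <- build_scene(protocol, seed = s)
  rec      <- simulate_acquisition(scene, seed = s + 1000)
  run_bci_pipeline(rec, protocol)$cv$mean_accuracy
}, numeric(1))
round(accs, 3)
#>  [1] 0.567 0.767 0.783 0.650 0.717 0.733 0.767 0.817 0.733 0.633
t.test(accs, mu = 0.5, alternative = "greater")$p.value
#> [1] 4.876983e-06
```

a mean single-trial accuracy of 0.717 across ten sessions, with the
average HbO response peaking ≈ 10.4 s after task onset.

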