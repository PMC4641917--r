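---
title: "Modeling a modular CW-fNIRS instrument and its single-trial BCI analysis"
author: "fnirsim authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling a modular CW-fNIRS instrument and its single-trial BCI analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fnirsim)
```

## What the package models

Continuous-wave functional near-infrared spectroscopy (fNIRS) measures
cerebral oxygenation by shining near-infrared light of two wavelengths
(here 750 and 850 nm) into the scalp and detecting the back-scattered
intensity a few centimeters away. Changes in the concentrations of
oxygenated (HbO) and deoxygenated (HbR) hemoglobin change the tissue's
absorption, and — because the two chromophores have different extinction
spectra — measuring at two wavelengths lets both be estimated through the
modified Beer–Lambert law (MBLL).

`fnirsim` is a digital twin of a modular, lock-in-based CW-fNIRS
instrument and of the single-trial mental-arithmetic brain–computer
interface (BCI) analysis used to validate such instruments. It simulates
the electronics end to end (LED square-wave modulation, photodetection
with shot and dark noise, programmable gain, square-wave lock-in
demodulation with phase-shift attenuation, time-division multiplexing,
16-bit quantization), re-derives the instrument's bench characterization
figures analytically, and runs the complete physiological analysis chain
on synthetic ground-truth physiology. Because the physiology is synthetic
and known, every stage of the analysis can be validated against the truth
that generated the data.

## The instrument model

### Lock-in demodulation and phase-shift attenuation

The LEDs are square-wave modulated at $f_{mod} = 3.125$ kHz and the
detected signal is demodulated against the same reference, shifting the
physiological information away from low-frequency noise (dark current,
stray light, $1/f$). Propagation delays in the analog signal path shift
the detected waveform against the reference; with the total mismatch
measured as the sum of the rising- and falling-edge delays
$\Delta t = t_{dr} + t_{df}$, the standard analytic model for square-wave
lock-in detection gives an effective gain

$$A = \cos(\Delta\Phi), \qquad \Delta\Phi = \frac{2\pi\,\Delta t}{T},$$

which is $A \approx 0.875$ at the instrument's measured delays
($18.5 + 7.2\,\mu s$ against $T = 320\,\mu s$).

A modeling choice worth stating explicitly: multiplying the *full*
square-modulated signal (with all its harmonics) by a delayed square
reference would produce a triangular phase response, $1 - 2\Delta t/T$.
The cosine law is the narrowband model — it describes the demodulation of
the signal component at the reference frequency, which is where the
physiological information lives after modulation. The simulator therefore
mixes the detector waveform with the reference *fundamental* (a unit
sinusoid at $f_{mod}$), applies the 3rd-order Butterworth low-pass, and
scales so a zero-phase full-amplitude modulated input recovers its
envelope. This reproduces the cosine law exactly, matches the analytic
`attenuation_factor()` within 1 % across the sweep tests, and keeps the
brute-force mixing-and-averaging oracle and the analytic fast path in
agreement. Waveforms are evaluated on a midpoint time base (sample $k$ at
$(k - 0.5)/f_s$) so that discretized square edges remain symmetric and
the discrete mixing ratio is exactly $\cos\Delta\Phi$; the default
simulation rate is $20 \times f_{mod}$.

### Gains, noise and quantization

The programmable gain amplifier is modeled as the binary ladder
$0.6875 \times 2^k$, $k = 0..7$ (0.6875–88), followed by the fixed 5.1
post-filter gain. The detector contributes Gaussian dark noise
(300 µVrms over its 14 kHz bandwidth), an optional static dark offset,
and a shot-noise term whose standard deviation grows as $\sqrt{P}$. In
the per-slot acquisition path the lock-in low-pass (default 100 Hz,
configurable; the hardware value is not part of the instrument's printed
record) reduces the noise reaching the sampler by the square root of the
bandwidth ratio. The ADC is unipolar 0–2.5 V, 16 bit, with clamping as
the defined out-of-range behavior and a conversion time of 80.3 ms per
slot, which — together with the configurable dwell time (default 24 ms) —
sets the per-channel-wavelength sampling rate: a one-module, two-channel
probe yields $1/(4 \times 104.3\ \mathrm{ms}) \approx 2.4$ Hz.

### Channel scheduling

Channels are time-division multiplexed. The 4-bit control interface
(RST, TRIG, CH1, CH0) is modeled as a state machine: CH1:CH0 select a
channel, each TRIG rising edge activates it — 750 nm first after any
reset, then alternating 750/850 — and RST high turns everything off and
re-arms the 750 nm start. The channel-select lines are latched at the
TRIG edge (the hardware's setup/hold behavior is not specified; latching
at the edge is the simplest consistent semantics). The encoder emits an
RST pulse before each 750 nm slot so the decoder's wavelength toggle
stays aligned with the schedule regardless of slot history. The dwell
time is inserted after channel activation and before sampling.

## The synthetic study

The generator emulates a frontal mental-arithmetic block design: 30 task
trials of 10 s, each followed by a pause drawn uniformly from 25–30 s,
one longer rest (default 60 s) after the 15th trial whose data is never
analyzed, a 30 s lead-in that provides the intensity baseline, and a 5 s
tail so the last analysis window stays inside the recording. Two emitter
channels (Fp1, Fp2) and one detector (AFz) at 3.5 cm separation are
assumed.

The task-locked response is a double-gamma kernel convolved with the
task boxcar. The kernel is parameterized by the modes of its two lobes
(`peak_time`, default 5 s; `undershoot_time`, 16 s; undershoot ratio
1/6) and a dispersion `time_scale` (default 2.5 s). These defaults were
chosen, once, so that the simulated block response reproduces the
qualitative features reported for frontal mental arithmetic with this
class of instrument: the HbO block response peaks ≈ 11 s after task
onset (an "increase peaking after approximately 10 s"), is still
developing during the 5–15 s analysis window — the premise that makes
slope features informative — and returns to baseline gradually through
the following pause rather than collapsing at task offset. A narrower,
faster-returning kernel (e.g. the rate-1 gamma pair often used for BOLD
modeling) would contradict that phenomenology: its response is back near
baseline within a few seconds of task end, which empties both analysis
windows of discriminative slope. The between-trial return time constant
is a free parameter of the model, not a fitted quantity. HbR is modeled
as a scaled opposite-signed copy (default ratio −0.3); its amplitude is
plotted but not quantified in the instrument literature this emulates.

On top of the response, each channel receives: a cardiac pulse sinusoid
(1.2 Hz) with amplitude equal to the hemodynamic amplitude (1 µM) —
pulse artifacts of the order of the metabolic signal are themselves a
signal-quality indicator for this class of device; a slow systemic
(Mayer-wave-like) oscillation (0.1 Hz, 0.3 µM); white measurement noise
(0.3 µM per sample at the scene rate of 12.5 Hz); and a linear drift
(0.001 µM/s). Pulse, slow wave and drift enter HbR scaled by the HbR/HbO
ratio, mimicking their shared vascular origin; white noise is
independent per chromophore. Channel-specific random phases decorrelate
the systemic components across channels. Scenes are pure functions of
(parameters, seed).

What the generator does *not* emulate: motion artifacts and optode
decoupling, scalp-versus-cortex partial volume effects, subject-specific
HRF variability, multi-layer photon transport, and correlated
non-stationary physiological noise. Passing the end-to-end tests
therefore shows that the analysis chain is implemented correctly and
recovers known structure at realistic SNR — not that the instrument
would achieve any particular accuracy on real subjects.

## The MBLL layer

Concentration changes map to optical density changes as
$\Delta OD(\lambda) = (\varepsilon_{\lambda,HbO}\,\Delta HbO +
\varepsilon_{\lambda,HbR}\,\Delta HbR)\, d\, \mathrm{DPF}$, with
source-detector distance $d = 3.5$ cm and differential pathlength factor
DPF = 6 (a common adult forehead value; configurable). The extinction
table ships standard tabulated molar extinction values (750 nm:
HbO 5.18×10⁻⁴, HbR 1.405×10⁻³; 850 nm: HbO 1.058×10⁻³, HbR
6.91×10⁻⁴ cm⁻¹µM⁻¹) and is overridable; the inversion only requires the
2×2 system to be well conditioned, and the constructor rejects
numerically singular tables. Transmitted power is attenuated by a
configurable broadband tissue loss (default 60 dB) times $10^{-\Delta
OD}$. The inversion references intensities to the mean of the first 5 s
of the recording (the recording's lead-in rest; the choice of baseline
window is a convention, not physics). Forward and inverse are exact
inverses; the test suite holds them to $10^{-9}$ relative error.

## The analysis pipeline

The preprocessing chain follows the standard simple single-trial fNIRS
recipe: linear detrending in consecutive non-overlapping 300 s windows
(the trailing partial window is detrended too), subtraction of a
centered ±30 s moving average (window truncated at the series edges,
current sample included), and an order-6 elliptic IIR low-pass at 0.5 Hz
with 0.5 dB passband ripple and 40 dB stopband attenuation. Ripple and
stopband depth are conventions of this implementation — only order and
cutoff are part of the recipe. Filtering is applied forward–backward:
zero-phase filtering avoids group-delay distortion of the trial windows,
at the cost of applying the magnitude response twice (DC sits ≈ 1 dB
below unity rather than 0.5 dB; irrelevant after baseline-referencing
and slope fitting, both of which are offset-free).

Trials are extracted as: task windows $[onset + 5, onset + 15)$ s (the
response has developed by then) and pause windows covering the last 10 s
of each pause (hemoglobin has returned toward baseline). Long-rest data
is excluded. Each trial contributes one least-squares slope per channel
and chromophore (4 features for the two-channel probe). Classification
is linear discriminant analysis with pooled covariance, equal priors and
a small ridge ($10^{-8}$ of the mean covariance diagonal) for numerical
safety, evaluated under stratified 10-fold cross-validation with a
seeded fold shuffle (stratification keeps fold class ratios balanced;
the recipe this follows does not specify it). Significance against the
0.5 chance level of the balanced two-class problem is a one-sided t-test
across fold accuracies, computed per recording; when fold accuracies are
all identical the p-value degenerates to 0 or 1 by the sign of the mean.
The average hemodynamic response is the sample-wise mean ± standard
error across trials on a $[-5, +25]$ s window, referenced to the mean of
the pre-onset segment.

## The characterization layer

The bench mathematics are implemented as pure functions of the measured
inputs: attenuation $A = \cos(2\pi\Delta t/T)$; noise-equivalent power
$NEP = (\mu_d + \sigma_d)/(R_\lambda\,G_{total})$ from the dark level at
the lock-in output; signal-to-noise distance
$20\log_{10}(P_{incident}/NEP_{pp})$; saturation
$V_{ADC}/(G_{min}\,G_{filter}\,R_\lambda)$; dynamic range
$20\log_{10}(P_{sat}/NEP_{pp})$; and the fNIRS margin
$SNR - L_{tissue} + 20\log_{10}(f_{signal})$ with 60 dB tissue loss and
a 1 % signal fraction. Two conventions are fixed deliberately:
peak-to-peak and rms quantities are related by $2\sqrt{2}$ throughout,
and all dB figures use $20\log_{10}$ of the (voltage-equivalent) power
ratio — this is the arithmetic behind the instrument's quoted
128 dB / 55.13 dB figures, and the report is only consistent if used
end-to-end. Evaluating the NEP formula at the recorded dark levels
($\mu_d = 0.101$ V, $\sigma_d = 3.99$ mV, $G = 44 \times 5.1$,
$R_{750} = 0.55$ V/µW) gives 0.851 nWrms at 750 nm, slightly above the
instrument's quoted 0.80 nWrms (at 850 nm the formula and the quoted
0.78 agree); the bench rounding behind that figure is not recoverable,
so `characterize()` reports the formula value and takes the *measured*
peak-to-peak NEPs (2.27/2.21 nWpp) as inputs for the downstream distance
and dynamic-range figures, as the bench evaluation did. Drift is
estimated by ordinary least squares on 20-minute raw recordings, with
stability expressed relative to the mean level of the analyzed window.

## Numerical choices and degenerate inputs

* ADC out-of-range inputs clamp (the rails are the defined behavior);
  quantization error is bounded by half an LSB in range.
* The lock-in demodulator requires a simulation rate of at least
  $10 f_{mod}$ and rejects lower rates.
* Scene construction rejects sampling rates below twice the pulse
  frequency (the *scene* must be alias-free; the instrument's slot
  sampling of the scene then aliases the pulse exactly as the physical
  instrument would, and the 0.5 Hz low-pass removes it).
* Trial windows that would extend past the end of the series are dropped
  with a warning rather than padded.
* `fit_drift` refuses fewer than two samples; `lda_crossval` refuses
  single-class inputs; the packet parser names the offending line.
* All stochastic operations take explicit seeds and restore the caller's
  RNG state; defaults are 0.

## Problem sizes

The shipped defaults keep everything desk-sized: a 30-trial session is
≈ 1330 s of scene at 12.5 Hz (two channels), ≈ 12,700 raw packets at the
2.4 Hz channel rate, and a full simulate–analyze round trip takes about
a second. The end-to-end validation aggregates 10 session seeds; drift
recovery uses 50 seeds of 20-minute recordings at 2.4 Hz. These sizes
are the package's test conditions, chosen to mirror the emulated study's
single-session scale.

## Known limitations

* The electronics model is behavioral, not circuit-level: no transient
  over/undershoot, no supply-coupling effects beyond the configurable
  drift term, no temperature coefficients.
* The "signal monitor" feedback line of the hardware concept is not
  modeled; gain selection is the user's responsibility.
* The square-wave modulation duty cycle is fixed at 50 %.
* The measured dark level $\mu_d$ is treated as a configurable offset
  plus noise; whether the bench figure contains an electronic offset is
  not recoverable from the instrument's record.
* Classification numbers obtained on synthetic physiology characterize
  the pipeline, not human performance; real-subject accuracies depend on
  factors the generator deliberately does not model.
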