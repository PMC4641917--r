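# Shared fixtures: small, fast synthetic objects built in code.

# A short deterministic protocol (fixed pause length so trial segments are
# sample-aligned and comparable across trials).
tiny_protocol <- function(n_trials = 3, pause = 28, seed = 1) {
  generate_protocol(n_trials, pause_range = c(pause, pause), seed = seed)
}

# A noiseless scene: pure hemodynamic response, no systemic components.
clean_scene <- function(protocol, n_channels = 2, fs = 12.5, seed = 1, ...) {
  build_scene(protocol, hrf_params(), n_channels = n_channels, fs = fs,
              pulse_amplitude = 0, slow_amplitude = 0, noise_sd = 0,
              drift_slope = 0, seed = seed, ...)
}

# Full default study for one seed: protocol + scene + recording.
default_study <- function(seed) {
  protocol <- generate_protocol(30, seed = seed)
  scene <- build_scene(protocol, seed = seed)
  recording <- simulate_acquisition(scene, seed = seed + 1000)
  list(protocol = protocol, scene = scene, recording = recording)
}

# Shuffle a vector under a fixed seed without touching the suite's RNG flow.
with_seed_sample <- function(x, seed) {
  withr::with_seed(seed, sample(x))
}

# Square-modulated waveform (0/amplitude envelope) on the midpoint time base.
modulated_square <- function(amplitude, f_mod, fs, n_periods) {
  n <- round(n_periods * fs / f_mod)
  t <- (seq_len(n) - 0.5) / fs
  amplitude * as.numeric((t * f_mod) %% 1 < 0.5)
}
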