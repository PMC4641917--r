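#' Generate a mental-arithmetic block-design experiment protocol
#'
#' Emulates the study design the instrument was validated with: `n_trials`
#' mental-arithmetic task blocks of 10 s, each followed by a pause drawn
#' uniformly from 25-30 s, and (when `n_trials` is large enough) one longer
#' rest after the 15th trial during which subjects rest and drink; no data
#' from that rest is used in analysis.
#'
#' @param n_trials number of task trials (>= 1); the study used 30.
#' @param task_duration task block length, seconds (default 10).
#' @param pause_range pause duration range, seconds (default `c(25, 30)`).
#' @param long_rest_after trial index after which the long rest is inserted
#'   (default 15; only when `n_trials > long_rest_after`).
#' @param long_rest_duration long-rest length, seconds (default 60; the study
#'   reports a "variable length" rest, so this is configurable).
#' @param lead_in initial rest before the first trial, seconds (default 30);
#'   gives the analysis a baseline segment.
#' @param tail_s post-session buffer after the final pause, seconds
#'   (default 5); keeps the last pause window inside the recording.
#' @param seed RNG seed for the pause durations.
#' @return an `experiment_protocol` object: data frame of events
#'   (`onset`, `duration`, `label` in task/pause/long_rest) with attribute
#'   `total_duration`.
#' @export
generate_protocol <- function(n_trials = 30L, task_duration = 10,
                              pause_range = c(25, 30), long_rest_after = 15L,
                              long_rest_duration = 60, lead_in = 30,
                              tail_s = 5, seed = 0L) {
  check_scalar(n_trials, "n_trials", lower = 1)
  check_scalar(task_duration, "task_duration", lower = 0, allow_equal_lower = FALSE)
  stopifnot(length(pause_range) == 2L, pause_range[1] <= pause_range[2])
  with_local_seed(seed, {
    onset <- numeric(); duration <- numeric(); label <- character()
    t <- lead_in
    for (i in seq_len(n_trials)) {
      onset <- c(onset, t); duration <- c(duration, task_duration)
      label <- c(label, "task")
      t <- t + task_duration
      p <- runif(1, pause_range[1], pause_range[2])
      onset <- c(onset, t); duration <- c(duration, p); label <- c(label, "pause")
      t <- t + p
      if (i == long_rest_after && n_trials > long_rest_after) {
        onset <- c(onset, t); duration <- c(duration, long_rest_duration)
        label <- c(label, "long_rest")
        t <- t + long_rest_duration
      }
    }
    events <- data.frame(onset = onset, duration = duration, label = label)
    structure(events, total_duration = t + tail_s,
              class = c("experiment_protocol", "data.frame"))
  })
}

#' Hemodynamic response parameters
#'
#' The task-locked response is a double-gamma kernel (response peak, later
#' undershoot) convolved with the 10 s task boxcar and scaled so the block
#' response maximum equals `hbo_amplitude`. `peak_time` and
#' `undershoot_time` are the modes of the two gamma lobes and `time_scale`
#' their dispersion; with the defaults the oxygenated-hemoglobin (HbO) block
#' response peaks just after 11 s from task onset — the "increase peaking
#' after approximately 10 s" typical of frontal mental arithmetic — is still
#' rising throughout the 5-15 s analysis window, and returns to baseline
#' gradually during the following pause. Deoxygenated hemoglobin (HbR) is
#' modeled as a scaled, opposite-signed copy.
#'
#' @param peak_time gamma-kernel mode of the response lobe, seconds
#'   (default 5).
#' @param undershoot_time mode of the undershoot lobe, seconds (default 16).
#' @param undershoot_ratio undershoot relative amplitude (default 1/6).
#' @param time_scale gamma dispersion (scale parameter), seconds
#'   (default 2.5); larger values widen the response and slow the return to
#'   baseline.
#' @param hbo_amplitude HbO block-response peak, micromolar (default 1).
#' @param hbr_amplitude HbR block-response peak, micromolar; must be opposite
#'   in sign and smaller in magnitude than HbO (default -0.3).
#' @return an `hrf_params` list.
#' @export
hrf_params <- function(peak_time = 5, undershoot_time = 16,
                       undershoot_ratio = 1 / 6, time_scale = 2.5,
                       hbo_amplitude = 1.0, hbr_amplitude = -0.3) {
  check_scalar(peak_time, "peak_time", lower = 0, allow_equal_lower = FALSE)
  check_scalar(undershoot_time, "undershoot_time", lower = 0, allow_equal_lower = FALSE)
  check_scalar(undershoot_ratio, "undershoot_ratio", lower = 0)
  check_scalar(time_scale, "time_scale", lower = 0, allow_equal_lower = FALSE)
  stopifnot(is.finite(hbo_amplitude), is.finite(hbr_amplitude))
  if (hbo_amplitude != 0) {
    r <- hbr_amplitude / hbo_amplitude
    if (!(r > -1 && r <= 0)) {
      stop_input("hbr_amplitude/hbo_amplitude must lie in (-1, 0], got %g", r)
    }
  }
  structure(list(peak_time = peak_time, undershoot_time = undershoot_time,
                 undershoot_ratio = undershoot_ratio, time_scale = time_scale,
                 hbo_amplitude = hbo_amplitude, hbr_amplitude = hbr_amplitude),
            class = "hrf_params")
}

# Double-gamma kernel sampled at fs; each lobe is a gamma density whose mode
# equals the requested time (shape = 1 + time/scale).
hrf_kernel <- function(hrf, fs, duration = 60) {
  t <- seq(0, duration, by = 1 / fs)
  sc <- hrf$time_scale
  dgamma(t, shape = 1 + hrf$peak_time / sc, scale = sc) -
    hrf$undershoot_ratio * dgamma(t, shape = 1 + hrf$undershoot_time / sc, scale = sc)
}

#' Task-locked hemodynamic concentration timecourses
#'
#' Convolves the protocol's task boxcar with the double-gamma kernel and
#' scales so a single task block attains `hbo_amplitude` at its peak.
#' Between trials the response decays back toward zero.
#'
#' @param protocol an [generate_protocol()] object.
#' @param hrf an [hrf_params()] object.
#' @param fs sampling rate, Hz.
#' @return a list with `t` (seconds), `hbo` and `hbr` (micromolar vectors).
#' @export
hemodynamic_response <- function(protocol, hrf = hrf_params(), fs = 12.5) {
  stopifnot(inherits(protocol, "experiment_protocol"))
  check_scalar(fs, "fs", lower = 0, allow_equal_lower = FALSE)
  total <- attr(protocol, "total_duration")
  t <- seq(0, total, by = 1 / fs)
  stim <- numeric(length(t))
  tasks <- protocol[protocol$label == "task", , drop = FALSE]
  for (i in seq_len(nrow(tasks))) {
    stim[t >= tasks$onset[i] & t < tasks$onset[i] + tasks$duration[i]] <- 1
  }
  kern <- hrf_kernel(hrf, fs)
  u <- convolve_causal(stim, kern) / fs
  # normalization: peak of one isolated task block of the protocol's duration
  block_dur <- if (nrow(tasks)) tasks$duration[1] else 10
  tb <- seq(0, block_dur + 40, by = 1 / fs)
  ub <- convolve_causal(as.numeric(tb < block_dur), kern) / fs
  norm <- max(ub)
  list(t = t,
       hbo = hrf$hbo_amplitude * u / norm,
       hbr = hrf$hbr_amplitude * u / norm)
}

# causal convolution truncated to length(x)
convolve_causal <- function(x, kern) {
  n <- length(x)
  stats::convolve(c(x, numeric(length(kern))), rev(kern), type = "open")[seq_len(n)]
}

#' Optical constants for the modified Beer-Lambert law
#'
#' Extinction coefficients for HbO and HbR at the instrument's two LED
#' wavelengths, the differential pathlength factor (DPF) and the
#' source-detector distance. The default extinction values are standard
#' tabulated molar extinction coefficients (expressed per micromolar and cm);
#' the MBLL itself only needs the 2x2 table to be well conditioned.
#'
#' @param extinction 2x2 matrix, rows `c("750","850")`, columns
#'   `c("HbO","HbR")`, units cm^-1 (umol/L)^-1.
#' @param dpf differential pathlength factor, dimensionless (default 6, a
#'   common adult forehead value).
#' @param distance source-detector distance, cm (default 3.5, the Fp1/Fp2 to
#'   AFz separation of the probe).
#' @param tissue_loss_db broadband optical loss of the head tissue, dB
#'   (default 60, the upper end of the 40-60 dB range assumed for adults).
#' @return an `optical_constants` list.
#' @export
optical_constants <- function(extinction = NULL, dpf = 6.0, distance = 3.5,
                              tissue_loss_db = 60) {
  if (is.null(extinction)) {
    extinction <- matrix(
      c(5.18e-4, 1.4052e-3,   # 750 nm: HbO, HbR
        1.058e-3, 6.913e-4),  # 850 nm: HbO, HbR
      nrow = 2, byrow = TRUE,
      dimnames = list(c("750", "850"), c("HbO", "HbR")))
  }
  stopifnot(is.matrix(extinction), all(dim(extinction) == c(2, 2)))
  if (abs(det(extinction)) < 1e-12) {
    stop_input("extinction table is numerically singular; MBLL inversion impossible")
  }
  check_scalar(dpf, "dpf", lower = 0, allow_equal_lower = FALSE)
  check_scalar(distance, "distance", lower = 0, allow_equal_lower = FALSE)
  check_scalar(tissue_loss_db, "tissue_loss_db", lower = 0)
  structure(list(extinction = extinction, dpf = dpf, distance = distance,
                 tissue_loss_db = tissue_loss_db),
            class = "optical_constants")
}

#' Modified Beer-Lambert forward model
#'
#' Maps chromophore concentration changes to the change in optical density
#' at one wavelength:
#' `dOD(lambda) = (eps(lambda,HbO) dHbO + eps(lambda,HbR) dHbR) * d * DPF`.
#' The transmitted power fraction is `10^(-tissue_loss_db/10) * 10^(-dOD)`.
#'
#' @param dhbo,dhbr concentration changes, micromolar (vectors).
#' @param constants an [optical_constants()] object.
#' @param wavelength 750 or 850 (nm).
#' @return a list with `dod` and `power_fraction` vectors.
#' @export
mbll_forward <- function(dhbo, dhbr, constants = optical_constants(),
                         wavelength = 750) {
  key <- wl_key(wavelength)
  eps <- constants$extinction[key, ]
  dod <- (eps[["HbO"]] * dhbo + eps[["HbR"]] * dhbr) *
    constants$distance * constants$dpf
  list(dod = dod,
       power_fraction = 10^(-constants$tissue_loss_db / 10) * 10^(-dod))
}

#' Assemble a synthetic physiology scene
#'
#' Stacks, per channel: the task-locked hemodynamic response, a pulse
#' sinusoid (cardiac artifact; the probe picks it up at an amplitude on the
#' order of the metabolic signal), a slow systemic (Mayer-wave-like)
#' oscillation, white measurement noise and a linear drift. Pulse, slow
#' oscillation and drift enter HbO directly and HbR scaled by the HbR/HbO
#' amplitude ratio, mimicking their shared vascular origin; white noise is
#' independent per chromophore. Channel-specific random phases decorrelate
#' the systemic components across channels.
#'
#' @param protocol an [generate_protocol()] object.
#' @param hrf an [hrf_params()] object.
#' @param n_channels number of optode channels (default 2: Fp1 and Fp2).
#' @param fs sampling rate of the scene, Hz (default 12.5; must exceed twice
#'   the pulse frequency).
#' @param pulse_freq cardiac frequency, Hz (default 1.2).
#' @param pulse_amplitude pulse artifact amplitude, micromolar (default 1.0,
#'   i.e. equal to the default hemodynamic amplitude).
#' @param slow_freq,slow_amplitude slow systemic oscillation (defaults
#'   0.1 Hz, 0.3 uM).
#' @param noise_sd white noise standard deviation per sample, micromolar
#'   (default 0.3).
#' @param drift_slope linear drift, micromolar per second (default 0.001).
#' @param seed RNG seed; the scene is a pure function of (parameters, seed).
#' @return a `physiology_scene` list: `t`, `fs`, matrices `hbo` and `hbr`
#'   (samples x channels, micromolar), the ground-truth `clean_hbo`/`clean_hbr`,
#'   `protocol`, `params`, `seed`.
#' @export
build_scene <- function(protocol = generate_protocol(), hrf = hrf_params(),
                        n_channels = 2L, fs = 12.5,
                        pulse_freq = 1.2, pulse_amplitude = 1.0,
                        slow_freq = 0.1, slow_amplitude = 0.3,
                        noise_sd = 0.3, drift_slope = 0.001,
                        seed = 0L) {
  check_scalar(n_channels, "n_channels", lower = 1)
  if (fs < 2 * pulse_freq) {
    stop_input("scene fs = %g Hz is below twice the pulse frequency (%g Hz); raise fs",
               fs, pulse_freq)
  }
  resp <- hemodynamic_response(protocol, hrf, fs)
  n <- length(resp$t)
  ratio <- if (hrf$hbo_amplitude != 0) hrf$hbr_amplitude / hrf$hbo_amplitude else 0
  with_local_seed(seed, {
    hbo <- matrix(0, n, n_channels)
    hbr <- matrix(0, n, n_channels)
    for (ch in seq_len(n_channels)) {
      ph_pulse <- runif(1, 0, 2 * pi)
      ph_slow <- runif(1, 0, 2 * pi)
      systemic <- pulse_amplitude * sin(2 * pi * pulse_freq * resp$t + ph_pulse) +
        slow_amplitude * sin(2 * pi * slow_freq * resp$t + ph_slow) +
        drift_slope * resp$t
      hbo[, ch] <- resp$hbo + systemic + rnorm(n, sd = noise_sd)
      hbr[, ch] <- resp$hbr + ratio * systemic + rnorm(n, sd = noise_sd)
    }
    structure(
      list(t = resp$t, fs = fs, hbo = hbo, hbr = hbr,
           clean_hbo = resp$hbo, clean_hbr = resp$hbr,
           protocol = protocol,
           params = list(n_channels = n_channels, pulse_freq = pulse_freq,
                         pulse_amplitude = pulse_amplitude,
                         slow_freq = slow_freq, slow_amplitude = slow_amplitude,
                         noise_sd = noise_sd, drift_slope = drift_slope,
                         hrf = hrf),
           seed = seed),
      class = "physiology_scene")
  })
}

#' @export
print.physiology_scene <- function(x, ...) {
  cat(sprintf("physiology scene: %d channel(s), %.1f Hz, %.0f s, %d task trials (seed %d)\n",
              ncol(x$hbo), x$fs, max(x$t),
              sum(x$protocol$label == "task"), x$seed))
  invisible(x)
}
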