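# Bench characterization mathematics: phase-shift attenuation,
# noise-equivalent power, signal-to-noise distance, saturation, dynamic
# range, fNIRS margin and drift estimation.
#
# dB convention used throughout: 20*log10 of the ratio of two optical
# powers, treating them as voltage-equivalent quantities at the detector
# output (responsivity is linear in power, so an optical power ratio maps
# 1:1 onto a voltage ratio). This is the convention behind the instrument's
# quoted 128 dB signal-to-noise distance and 55.13 dB dynamic range.

#' Lock-in timing measurement
#'
#' The total phase mismatch between reference and signal in square-wave
#' lock-in demodulation is measured as the sum of the rising- and
#' falling-edge delays between the two, `dt = t_dr + t_df`.
#'
#' @param t_dr,t_df rising/falling edge delays, seconds.
#' @param T_ref reference period, seconds (default 320e-6, i.e. 3.125 kHz).
#' @return a `timing_measurement` list.
#' @export
timing_measurement <- function(t_dr = 18.5e-6, t_df = 7.2e-6, T_ref = 320e-6) {
  check_scalar(t_dr, "t_dr", lower = 0)
  check_scalar(t_df, "t_df", lower = 0)
  check_scalar(T_ref, "T_ref", lower = 0, allow_equal_lower = FALSE)
  if (t_dr + t_df >= T_ref) stop_input("t_dr + t_df must be below the period")
  structure(list(t_dr = t_dr, t_df = t_df, T_ref = T_ref),
            class = "timing_measurement")
}

#' Phase-shift attenuation factor of square-wave lock-in demodulation
#'
#' `A = cos(2 pi (t_dr + t_df) / T)`: the gain loss caused by the phase
#' mismatch between reference and detected signal.
#'
#' @param tm a [timing_measurement()].
#' @return attenuation factor A (dimensionless, <= 1).
#' @examples
#' attenuation_factor(timing_measurement(18.5e-6, 7.2e-6, 320e-6))  # ~0.875
#' @export
attenuation_factor <- function(tm = timing_measurement()) {
  stopifnot(inherits(tm, "timing_measurement"))
  cos(2 * pi * (tm$t_dr + tm$t_df) / tm$T_ref)
}

#' Dark-noise measurement at the lock-in output
#'
#' @param mu_d mean dark voltage, Vrms (default 0.101, measured at PGA gain
#'   44 with the fixed 5.1 post-filter gain).
#' @param sigma_d dark voltage standard deviation, Vrms (default 3.99e-3).
#' @param g_total total gain during the measurement (default 44 * 5.1).
#' @return a `noise_measurement` list.
#' @export
noise_measurement <- function(mu_d = 0.101, sigma_d = 3.99e-3,
                              g_total = 44 * 5.1) {
  check_scalar(mu_d, "mu_d", lower = 0)
  check_scalar(sigma_d, "sigma_d", lower = 0)
  check_scalar(g_total, "g_total", lower = 0, allow_equal_lower = FALSE)
  structure(list(mu_d = mu_d, sigma_d = sigma_d, g_total = g_total),
            class = "noise_measurement")
}

#' Noise-equivalent power of the detection branch
#'
#' `NEP_rms = (mu_d + sigma_d) / (responsivity * g_total)` — the incident
#' optical power whose output equals the dark level, i.e. SNR = 1. The
#' peak-to-peak figure uses the fixed convention `pp = 2 sqrt(2) * rms`.
#'
#' @param nm a [noise_measurement()].
#' @param responsivity detector responsivity at the wavelength of interest,
#'   V/uW.
#' @return list with `nep_rms_nw` and `nep_pp_nw` (nanowatts).
#' @export
noise_equivalent_power <- function(nm = noise_measurement(),
                                   responsivity = 0.55) {
  stopifnot(inherits(nm, "noise_measurement"))
  check_scalar(responsivity, "responsivity", lower = 0, allow_equal_lower = FALSE)
  nep_uw <- (nm$mu_d + nm$sigma_d) / (responsivity * nm$g_total)
  list(nep_rms_nw = 1e3 * nep_uw, nep_pp_nw = 2 * sqrt(2) * 1e3 * nep_uw)
}

#' Signal-to-noise distance
#'
#' Ratio, in dB, of the optical power incident to the tissue to the smallest
#' power still distinguishable from the detection noise floor (the NEP).
#'
#' @param p_incident_mw incident power, mW.
#' @param nep_pp_nw noise-equivalent power, nW peak-to-peak.
#' @return distance in dB (`20 log10` of the power ratio).
#' @examples
#' snr_distance(5.70, 2.27)  # ~128 dB at 750 nm
#' @export
snr_distance <- function(p_incident_mw, nep_pp_nw) {
  check_scalar(p_incident_mw, "p_incident_mw", lower = 0, allow_equal_lower = FALSE)
  check_scalar(nep_pp_nw, "nep_pp_nw", lower = 0, allow_equal_lower = FALSE)
  20 * log10(p_incident_mw * 1e6 / nep_pp_nw)
}

#' Incident power that saturates the detection branch
#'
#' Saturation occurs when the ADC input limit is reached at the minimum PGA
#' gain: `P_sat = v_adc_max / (g_min * g_filter * responsivity)`.
#'
#' @param v_adc_max ADC input limit, V peak-to-peak (default 2.5).
#' @param g_min minimum PGA gain (default 0.6875).
#' @param g_filter fixed post-filter gain (default 5.1).
#' @param responsivity detector responsivity, V/uW.
#' @return saturating incident power, uW peak-to-peak.
#' @examples
#' saturation_power(responsivity = 0.55)  # ~1.296 uWpp at 750 nm
#' @export
saturation_power <- function(v_adc_max = 2.5, g_min = 0.6875, g_filter = 5.1,
                             responsivity = 0.55) {
  for (nm in c("v_adc_max", "g_min", "g_filter", "responsivity")) {
    check_scalar(get(nm), nm, lower = 0, allow_equal_lower = FALSE)
  }
  v_adc_max / (g_min * g_filter * responsivity)
}

#' Dynamic range of the detection branch
#'
#' Ratio, in dB, of the saturating incident power to the noise-equivalent
#' power.
#'
#' @param saturation_uwpp saturating power, uW peak-to-peak.
#' @param nep_pp_nw noise-equivalent power, nW peak-to-peak.
#' @return dynamic range in dB.
#' @examples
#' dynamic_range(1.296, 2.27)  # ~55.13 dB
#' @export
dynamic_range <- function(saturation_uwpp, nep_pp_nw) {
  check_scalar(saturation_uwpp, "saturation_uwpp", lower = 0, allow_equal_lower = FALSE)
  check_scalar(nep_pp_nw, "nep_pp_nw", lower = 0, allow_equal_lower = FALSE)
  20 * log10(saturation_uwpp * 1e3 / nep_pp_nw)
}

#' Margin between the physiological fNIRS signal and the noise floor
#'
#' Starting from the signal-to-noise distance, subtracts the optical loss of
#' the head tissue and the penalty for the metabolic fNIRS component being
#' only a small fraction of the measured optical signal:
#' `margin = snr - tissue_loss + 20 log10(signal_fraction)`.
#'
#' @param snr_db signal-to-noise distance, dB.
#' @param tissue_loss_db tissue optical loss, dB (default 60).
#' @param signal_fraction fNIRS fraction of the measured signal, in (0, 1]
#'   (default 0.01).
#' @return margin in dB.
#' @examples
#' fnirs_margin(128, 60, 0.01)  # ~28 dB
#' @export
fnirs_margin <- function(snr_db, tissue_loss_db = 60, signal_fraction = 0.01) {
  check_scalar(snr_db, "snr_db")
  check_scalar(tissue_loss_db, "tissue_loss_db", lower = 0)
  check_scalar(signal_fraction, "signal_fraction", lower = 0, upper = 1,
               allow_equal_lower = FALSE)
  snr_db - tissue_loss_db + 20 * log10(signal_fraction)
}

#' Estimate signal drift by linear least squares
#'
#' Fits an ordinary-least-squares line to a raw voltage recording (the
#' instrument's drift is specified from 20-minute continuous acquisitions)
#' and reports the slope plus the relative stability over the analyzed
#' window.
#'
#' @param samples voltage samples, V.
#' @param fs sampling rate, Hz.
#' @return list with `c_d` (drift coefficient, V/s), `stability_pct`
#'   (100 * c_d * duration / mean level) and `duration` (s).
#' @export
fit_drift <- function(samples, fs) {
  if (length(samples) < 2L) stop_input("need at least 2 samples to fit a drift")
  check_scalar(fs, "fs", lower = 0, allow_equal_lower = FALSE)
  t <- (seq_along(samples) - 1) / fs
  fit <- lm(samples ~ t)
  c_d <- unname(coef(fit)[2])
  duration <- t[length(t)]
  list(c_d = c_d,
       stability_pct = 100 * c_d * duration / mean(samples),
       duration = duration)
}

#' Assemble the full characterization report
#'
#' Combines the timing and dark-noise measurements with the bench-measured
#' LED powers, responsivities and noise-equivalent powers into the
#' instrument's performance table: attenuation factor, NEP (formula value),
#' signal-to-noise distance, saturation power, dynamic range, fNIRS margin
#' and (optionally) drift.
#'
#' The signal-to-noise and dynamic-range figures are computed from the
#' *measured* peak-to-peak NEPs (`measured_nep_pp_nw`), which were read off
#' the bench and differ slightly from the analytic
#' [noise_equivalent_power()] value (reported alongside); both appear in the
#' report.
#'
#' @param timing a [timing_measurement()].
#' @param noise a [noise_measurement()].
#' @param p_incident_mw named vector of incident LED powers, mW (defaults:
#'   the powers at 50 mA drive, 5.70 / 5.38 mW).
#' @param responsivity named vector, V/uW.
#' @param measured_nep_pp_nw named vector of bench NEPs, nW peak-to-peak
#'   (defaults 2.27 / 2.21).
#' @param v_adc_max,g_min,g_filter saturation inputs (defaults 2.5 Vpp,
#'   0.6875, 5.1).
#' @param tissue_loss_db,signal_fraction margin inputs (defaults 60 dB, 1%).
#' @param drift_samples,drift_fs optional raw recording for [fit_drift()].
#' @return a `characterization_report` list.
#' @export
characterize <- function(timing = timing_measurement(),
                         noise = noise_measurement(),
                         p_incident_mw = c("750" = 5.70, "850" = 5.38),
                         responsivity = c("750" = 0.55, "850" = 0.60),
                         measured_nep_pp_nw = c("750" = 2.27, "850" = 2.21),
                         v_adc_max = 2.5, g_min = 0.6875, g_filter = 5.1,
                         tissue_loss_db = 60, signal_fraction = 0.01,
                         drift_samples = NULL, drift_fs = NULL) {
  wl <- names(responsivity)
  nep_formula <- lapply(responsivity, function(r)
    noise_equivalent_power(noise, r))
  snr <- mapply(snr_distance, p_incident_mw[wl], measured_nep_pp_nw[wl])
  sat <- vapply(responsivity, function(r)
    saturation_power(v_adc_max, g_min, g_filter, r), numeric(1))
  dr <- mapply(dynamic_range, sat[wl], measured_nep_pp_nw[wl])
  margin <- vapply(snr, function(s)
    fnirs_margin(s, tissue_loss_db, signal_fraction), numeric(1))
  drift <- if (!is.null(drift_samples)) fit_drift(drift_samples, drift_fs) else NULL
  structure(
    list(attenuation = attenuation_factor(timing),
         nep_rms_nw = vapply(nep_formula, `[[`, numeric(1), "nep_rms_nw"),
         nep_pp_nw = vapply(nep_formula, `[[`, numeric(1), "nep_pp_nw"),
         measured_nep_pp_nw = measured_nep_pp_nw,
         snr_distance_db = snr, saturation_uwpp = sat,
         dynamic_range_db = dr, fnirs_margin_db = margin,
         drift = drift),
    class = "characterization_report")
}

#' @export
print.characterization_report <- function(x, ...) {
  cat("Instrument characterization\n")
  cat(sprintf("  lock-in phase-shift attenuation A: %.3f\n", x$attenuation))
  for (wl in names(x$snr_distance_db)) {
    cat(sprintf("  %s nm: NEP %.3f nWrms (formula) / %.2f nWpp (measured) | SNR distance %.1f dB | saturation %.3f uWpp | dynamic range %.2f dB | fNIRS margin %.1f dB\n",
                wl, x$nep_rms_nw[[wl]], x$measured_nep_pp_nw[[wl]],
                x$snr_distance_db[[wl]], x$saturation_uwpp[[wl]],
                x$dynamic_range_db[[wl]], x$fnirs_margin_db[[wl]]))
  }
  if (!is.null(x$drift)) {
    cat(sprintf("  drift: %.3g V/s (stability %.3f %% over %.0f s)\n",
                x$drift$c_d, x$drift$stability_pct, x$drift$duration))
  }
  invisible(x)
}

#' Render a characterization report as a data frame (one row per wavelength)
#' @param x a `characterization_report`.
#' @param ... unused.
#' @return a data frame suitable for CSV export.
#' @export
as.data.frame.characterization_report <- function(x, ...) {
  wl <- names(x$snr_distance_db)
  data.frame(
    wavelength_nm = as.numeric(wl),
    attenuation = x$attenuation,
    nep_rms_nw = as.numeric(x$nep_rms_nw[wl]),
    nep_pp_nw = as.numeric(x$nep_pp_nw[wl]),
    measured_nep_pp_nw = as.numeric(x$measured_nep_pp_nw[wl]),
    snr_distance_db = as.numeric(x$snr_distance_db[wl]),
    saturation_uwpp = as.numeric(x$saturation_uwpp[wl]),
    dynamic_range_db = as.numeric(x$dynamic_range_db[wl]),
    fnirs_margin_db = as.numeric(x$fnirs_margin_db[wl]),
    drift_v_per_s = if (is.null(x$drift)) NA_real_ else x$drift$c_d,
    row.names = NULL)
}
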