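test_that("phase-shift attenuation factor matches the timing arithmetic", {
  expect_equal(round(attenuation_factor(
    timing_measurement(18.5e-6, 7.2e-6, 320e-6)), 3), 0.875)
  expect_equal(attenuation_factor(timing_measurement(0, 0, 320e-6)), 1.0)
  expect_equal(attenuation_factor(timing_measurement(40e-6, 40e-6, 320e-6)),
               0, tolerance = 1e-12)  # dt = T/4
  expect_error(timing_measurement(200e-6, 200e-6, 320e-6), "below the period")
})

test_that("attenuation factor agrees with the numeric lock-in simulation", {
  fs <- 20 * 3125
  x <- modulated_square(1, 3125, fs, 100)
  lk0 <- lockin_config(t_dr = 0, t_df = 0)
  base <- fnirsim:::demodulated_mean(x, fs, lk0, phase_offset = 0)
  offsets <- seq(0, 45e-6, length.out = 10)
  for (dt in offsets) {
    tm <- timing_measurement(dt, 0, 320e-6)
    analytic <- attenuation_factor(tm)
    numeric_gain <- fnirsim:::demodulated_mean(
      x, fs, lk0, phase_offset = 2 * pi * dt / 320e-6) / base
    expect_equal(numeric_gain, analytic, tolerance = 0.02)
  }
})

test_that("noise-equivalent power follows the dark-level formula", {
  nep <- noise_equivalent_power(noise_measurement(0.101, 3.99e-3, 44 * 5.1), 0.55)
  # direct evaluation: (0.101 + 0.00399) / (0.55 * 224.4) uW = 0.8507 nWrms
  expect_equal(nep$nep_rms_nw, (0.101 + 0.00399) / (0.55 * 224.4) * 1e3,
               tolerance = 1e-12)
  expect_equal(nep$nep_rms_nw, 0.8507, tolerance = 1e-4)
  expect_equal(nep$nep_pp_nw, 2 * sqrt(2) * nep$nep_rms_nw)

  expect_equal(noise_equivalent_power(noise_measurement(0, 0, 224.4), 0.55)$nep_rms_nw, 0)
  half <- noise_equivalent_power(noise_measurement(0.101, 3.99e-3, 2 * 44 * 5.1), 0.55)
  expect_equal(half$nep_rms_nw, nep$nep_rms_nw / 2)
  expect_error(noise_measurement(g_total = 0), "g_total")
})

test_that("signal-to-noise distances reproduce the measured powers and NEPs", {
  expect_equal(snr_distance(5.70, 2.27), 128.0, tolerance = 0.05)
  expect_equal(snr_distance(5.38, 2.21), 127.7, tolerance = 0.05)
  expect_equal(snr_distance(1e-6, 1), 0)  # 1 nW vs 1 nW
  expect_error(snr_distance(0, 1), "p_incident")
})

test_that("saturation power and dynamic range follow the gain arithmetic", {
  expect_equal(saturation_power(2.5, 0.6875, 5.1, 0.55), 1.296, tolerance = 5e-4)
  expect_equal(saturation_power(2.5, 0.6875, 5.1, 0.60), 1.188, tolerance = 5e-4)
  expect_equal(saturation_power(2.5, 0.6875, 5.1, 1.10),
               saturation_power(2.5, 0.6875, 5.1, 0.55) / 2)

  expect_equal(dynamic_range(1.296, 2.27), 55.13, tolerance = 0.005)
  expect_equal(round(dynamic_range(1.188, 2.21), 1), 54.6)
  expect_equal(dynamic_range(1e-3, 1), 0)  # saturation equals NEP
})

test_that("fNIRS margin stacks SNR distance, tissue loss and signal fraction", {
  expect_equal(fnirs_margin(128, 60, 0.01), 28)
  expect_equal(fnirs_margin(127.7, 60, 0.01), 27.7)
  expect_equal(fnirs_margin(100, 0, 1.0), 100)
  expect_error(fnirs_margin(128, 60, 0), "signal_fraction")
})

test_that("dB arithmetic is internally consistent on randomized inputs", {
  set.seed(21)
  for (i in 1:20) {
    p <- runif(1, 0.5, 20); nep <- runif(1, 0.5, 10); b <- runif(1, 1.5, 10)
    expect_equal(snr_distance(p * b, nep),
                 snr_distance(p, nep) + 20 * log10(b), tolerance = 1e-9)
    expect_equal(dynamic_range(p, nep) - dynamic_range(p, nep * b),
                 -20 * log10(1 / b), tolerance = 1e-9)
  }
})

test_that("drift fitting recovers slope exactly on clean data", {
  fs <- 10
  t <- (0:11999) / fs
  d <- fit_drift(0.3 - 1e-6 * t, fs)
  expect_equal(d$c_d, -1e-6, tolerance = 1e-12)
  expect_equal(fit_drift(rep(0.42, 100), fs)$c_d, 0, tolerance = 1e-15)
  expect_error(fit_drift(0.3, fs), "at least 2")
})

test_that("drift recovery from noisy 20-min recordings is unbiased within 5%", {
  fs <- 2.4
  n <- round(20 * 60 * fs)
  t <- (seq_len(n) - 1) / fs
  slopes <- vapply(1:50, function(s) {
    set.seed(s)
    x <- 0.3 - 1e-6 * t + rnorm(n, sd = 4e-3)
    fit_drift(x, fs)$c_d
  }, numeric(1))
  expect_equal(mean(slopes), -1e-6, tolerance = 0.05)
  # stability over the window referenced to the mean level
  d <- fit_drift(0.3 - 1e-6 * t, fs)
  expect_equal(d$stability_pct, 100 * d$c_d * d$duration / mean(0.3 - 1e-6 * t),
               tolerance = 1e-9)
})

test_that("the characterization report collects all figures coherently", {
  rep <- characterize()
  expect_equal(round(rep$attenuation, 3), 0.875)
  expect_equal(unname(rep$snr_distance_db["750"]), 128.0, tolerance = 0.05)
  expect_equal(unname(rep$snr_distance_db["850"]), 127.7, tolerance = 0.05)
  expect_equal(unname(rep$saturation_uwpp["750"]), 1.296, tolerance = 5e-4)
  expect_equal(unname(rep$dynamic_range_db["750"]), 55.13, tolerance = 0.005)
  expect_equal(unname(rep$fnirs_margin_db["750"]), 28, tolerance = 0.05)
  # pp/rms convention holds throughout
  expect_equal(unname(rep$nep_pp_nw / rep$nep_rms_nw), rep(2 * sqrt(2), 2))
  # dynamic range cannot exceed the signal-to-noise distance
  expect_true(all(rep$dynamic_range_db <= rep$snr_distance_db))
  df <- as.data.frame(rep)
  expect_equal(nrow(df), 2)
  expect_true(all(c("snr_distance_db", "dynamic_range_db") %in% names(df)))
})
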