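test_that("LED power interpolates the bench-measured anchor points", {
  expect_equal(led_power(emitter_config(127.5), 750), 5.70)   # 50 mA
  expect_equal(led_power(emitter_config(255), 850), 10.30)    # 100 mA
  expect_equal(led_power(emitter_config(255), 750), 11.10)
  expect_equal(led_power(emitter_config(0), 750), 0)
  expect_error(led_power(emitter_config(100), 800), "wavelength")
  expect_error(emitter_config(300), "dac_level")
})

test_that("photodetection is linear in power with sqrt-power shot noise", {
  expect_equal(detect(1, wavelength = 750, noise = FALSE), 0.55)
  expect_equal(detect(2, wavelength = 850, noise = FALSE), 1.20)
  expect_equal(detect(0, wavelength = 750, noise = FALSE), 0)
  expect_error(detect(-1, wavelength = 750), "non-negative")

  # quadrupling the power doubles the shot-noise sd (dark noise off)
  cfg <- detector_config(dark_noise_rms = 0, shot_coeff = 1e-3)
  n <- 20000
  v1 <- detect(rep(1, n), cfg, 750, seed = 1) - 0.55
  v4 <- detect(rep(4, n), cfg, 750, seed = 2) - 4 * 0.55
  expect_equal(sd(v4) / sd(v1), 2, tolerance = 0.05)
})

test_that("ADC clamps, quantizes to 16 bits, and loses at most half an LSB", {
  adc <- adc_config()
  expect_equal(digitize(2.5, adc), 65535L)
  expect_equal(digitize(3.0, adc), 65535L)
  expect_equal(digitize(-0.1, adc), 0L)
  expect_true(abs(digitize(1.25, adc) - 32768L) <= 1L)

  set.seed(3)
  v <- runif(5000, 0, 2.5)
  err <- abs(dequantize(digitize(v, adc), adc) - v)
  expect_lte(max(err), 0.5 * 2.5 / 65535 + 1e-12)
})

test_that("lock-in demodulation recovers the envelope and follows cos(phase)", {
  lk <- lockin_config(t_dr = 0, t_df = 0)
  g <- gain_chain(pga_gain = 0.6875, post_filter_gain = 1)
  fs <- 20 * lk$f_mod
  a <- 0.3
  x <- modulated_square(a, lk$f_mod, fs, 400)

  # zero phase: output matches the brute-force mixing-and-averaging oracle
  y <- lock_in_demodulate(x, fs, lk, g, phase_offset = 0)
  mid <- y[seq(length(y) * 0.3, length(y) * 0.7)]
  oracle <- fnirsim:::demodulated_mean(x, fs, lk, phase_offset = 0)
  expect_equal(mean(mid), 0.6875 * oracle, tolerance = 1e-3)
  expect_equal(mean(mid), 0.6875 * a, tolerance = 0.01)

  # quadrature: output vanishes
  yq <- lock_in_demodulate(x, fs, lk, g, phase_offset = pi / 2)
  expect_lt(abs(mean(yq[seq(length(yq) * 0.3, length(yq) * 0.7)])), 1e-3 * a)

  # the measured edge delays attenuate by ~0.875
  phi <- 2 * pi * 25.7e-6 / 320e-6
  yp <- lock_in_demodulate(x, fs, lk, g, phase_offset = phi)
  ratio <- mean(yp[seq(length(yp) * 0.3, length(yp) * 0.7)]) / mean(mid)
  expect_equal(ratio, 0.875, tolerance = 0.005)

  expect_error(lock_in_demodulate(x, 5 * lk$f_mod, lk, g), "simulation rate")
})

test_that("lock-in gain vs phase matches cos over [0, pi/3] within 1%", {
  lk <- lockin_config(t_dr = 0, t_df = 0)
  fs <- 20 * lk$f_mod
  x <- modulated_square(1, lk$f_mod, fs, 200)
  for (phi in seq(0, pi / 3, length.out = 9)) {
    gain <- fnirsim:::demodulated_mean(x, fs, lk, phase_offset = phi) /
      fnirsim:::demodulated_mean(x, fs, lk, phase_offset = 0)
    expect_equal(gain, cos(phi), tolerance = 0.01)
  }
})

test_that("demodulated output is linear in modulation amplitude", {
  lk <- lockin_config(t_dr = 0, t_df = 0)
  fs <- 20 * lk$f_mod
  amps <- 10^seq(-2, -1, length.out = 8)  # one decade
  outs <- vapply(amps, function(a)
    fnirsim:::demodulated_mean(modulated_square(a, lk$f_mod, fs, 100), fs, lk,
                               phase_offset = 0),
    numeric(1))
  expect_gt(stats::cor(outs, amps)^2, 0.9999)
})

test_that("TDM acquisition is deterministic and respects Beer-Lambert scaling", {
  p <- tiny_protocol(1)
  scene <- clean_scene(p, fs = 12.5)
  scene$hbo[] <- 0; scene$hbr[] <- 0
  sched <- build_tdm_schedule(1, 2)

  r0 <- simulate_acquisition(scene, sched, noise = FALSE, duration = 30)
  for (wl in c(750, 850)) {
    codes <- r0$adc_code[r0$wavelength == wl]
    expect_equal(length(unique(codes)), 1L)  # constant baseline stream
  }

  r1 <- simulate_acquisition(scene, sched, seed = 9, duration = 30)
  r2 <- simulate_acquisition(scene, sched, seed = 9, duration = 30)
  expect_identical(r1$adc_code, r2$adc_code)

  # a known concentration step maps to an intensity ratio of 10^(-dOD)
  step <- scene
  half <- scene$t > max(scene$t) / 2
  step$hbo[half, ] <- 2.0
  rs <- simulate_acquisition(step, sched, noise = FALSE)
  const <- attr(rs, "constants")
  for (wl in c(750, 850)) {
    v <- dequantize(rs$adc_code[rs$channel == 0 & rs$wavelength == wl],
                    attr(rs, "config")$adc)
    expected <- 10^(-mbll_forward(2, 0, const, wl)$dod)
    measured <- utils::tail(v, 3)[1] / v[1]
    expect_equal(measured, expected, tolerance = 1e-3)
  }

  expect_error(simulate_acquisition(scene, sched, duration = 1e4), "exceeds")
})

test_that("analytic and waveform acquisition paths agree within 0.5%", {
  p <- tiny_protocol(1)
  scene <- clean_scene(p, fs = 12.5)
  sched <- build_tdm_schedule(1, 2)
  ra <- simulate_acquisition(scene, sched, noise = FALSE, duration = 10,
                             method = "analytic")
  rw <- simulate_acquisition(scene, sched, noise = FALSE, duration = 10,
                             method = "waveform")
  expect_equal(rw$volts, ra$volts, tolerance = 5e-3)
})
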