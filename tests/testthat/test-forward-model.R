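test_that("protocol generator reproduces the block design", {
  p <- generate_protocol(30, seed = 3)
  expect_equal(sum(p$label == "task"), 30)
  expect_equal(sum(p$label == "pause"), 30)
  expect_equal(sum(p$label == "long_rest"), 1)
  expect_true(all(p$duration[p$label == "task"] == 10))
  pauses <- p$duration[p$label == "pause"]
  expect_true(all(pauses >= 25 & pauses <= 30))
  # the long rest follows the 15th trial's pause
  i_rest <- which(p$label == "long_rest")
  expect_equal(sum(p$label[seq_len(i_rest)] == "task"), 15)
  # events are time-ordered and non-overlapping
  expect_true(all(diff(p$onset) > 0))
  expect_true(all(utils::head(p$onset + p$duration, -1) <= p$onset[-1] + 1e-9))

  p1 <- generate_protocol(1, seed = 3)
  expect_equal(sum(p1$label == "long_rest"), 0)

  expect_identical(generate_protocol(10, seed = 9), generate_protocol(10, seed = 9))
  expect_error(generate_protocol(0), "n_trials")
})

test_that("task-locked response peaks 8-12 s after onset and is time-invariant", {
  p <- tiny_protocol(2, pause = 100)  # separation beyond the kernel support
  r <- hemodynamic_response(p, hrf_params(), fs = 12.5)
  on <- p$onset[p$label == "task"]
  seg <- r$t >= on[1] & r$t <= on[1] + 25
  t_peak <- r$t[seg][which.max(r$hbo[seg])] - on[1]
  expect_gt(t_peak, 8)
  expect_lt(t_peak, 12)
  # HbR is opposite-signed and smaller
  expect_lt(min(r$hbr[seg]), 0)
  expect_lt(max(abs(r$hbr)), max(abs(r$hbo)))
  # identical, well-separated trials give identical response segments
  i1 <- which(r$t >= on[1])[1] + 0:125
  i2 <- which(r$t >= on[2])[1] + 0:125
  expect_equal(r$hbo[i1], r$hbo[i2], tolerance = 1e-6)

  z <- hemodynamic_response(p, hrf_params(hbo_amplitude = 0, hbr_amplitude = 0), 12.5)
  expect_true(all(z$hbo == 0) && all(z$hbr == 0))
})

test_that("MBLL forward model computes optical densities directly", {
  # zero concentration change -> zero dOD at both wavelengths
  for (wl in c(750, 850)) {
    expect_equal(mbll_forward(0, 0, wavelength = wl)$dod, 0)
  }
  # single-chromophore arithmetic: eps * dC * d * DPF
  eps <- matrix(c(1e-3, 0, 0, 1e-3), nrow = 2, byrow = TRUE,
                dimnames = list(c("750", "850"), c("HbO", "HbR")))
  const <- optical_constants(eps, dpf = 6, distance = 3.5, tissue_loss_db = 0)
  expect_equal(mbll_forward(1, 0, const, 750)$dod, 0.021)
  expect_equal(mbll_forward(1, 0, const, 750)$power_fraction, 10^(-0.021))
  expect_error(mbll_forward(1, 0, const, 800), "wavelength")
})

test_that("MBLL forward and inverse are exact inverses", {
  const <- optical_constants()
  inv <- mbll_invert(mbll_forward(1.0, -0.3, const, 750)$dod,
                     mbll_forward(1.0, -0.3, const, 850)$dod, const)
  expect_equal(inv$hbo, 1.0, tolerance = 1e-12)
  expect_equal(inv$hbr, -0.3, tolerance = 1e-12)

  set.seed(11)
  dc <- matrix(rnorm(2000), ncol = 2)
  dod750 <- mbll_forward(dc[, 1], dc[, 2], const, 750)$dod
  dod850 <- mbll_forward(dc[, 1], dc[, 2], const, 850)$dod
  back <- mbll_invert(dod750, dod850, const)
  rel <- abs(cbind(back$hbo, back$hbr) - dc) / pmax(abs(dc), 1e-30)
  expect_lt(max(rel), 1e-9)
})

test_that("scene generation is pure in (parameters, seed) and layers noise", {
  p <- tiny_protocol(2)
  s1 <- build_scene(p, seed = 5)
  s2 <- build_scene(p, seed = 5)
  expect_identical(s1$hbo, s2$hbo)
  expect_identical(s1$hbr, s2$hbr)

  clean <- clean_scene(p)
  expect_equal(clean$hbo[, 1], clean$clean_hbo, tolerance = 1e-12)
  expect_equal(clean$hbr[, 2], clean$clean_hbr, tolerance = 1e-12)

  expect_error(build_scene(p, fs = 2, pulse_freq = 1.2), "pulse frequency")
})

test_that("default scene has a spectral peak at the pulse frequency", {
  p <- tiny_protocol(3)
  s <- build_scene(p, seed = 2)
  x <- s$hbo[, 1] - mean(s$hbo[, 1])
  sp <- stats::spec.pgram(stats::ts(x, frequency = s$fs), plot = FALSE,
                          taper = 0, detrend = TRUE)
  in_band <- sp$freq > 1.1 & sp$freq < 1.3
  neighbors <- (sp$freq > 0.8 & sp$freq < 1.05) | (sp$freq > 1.35 & sp$freq < 1.6)
  expect_gt(max(sp$spec[in_band]), 10 * stats::median(sp$spec[neighbors]))
})
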