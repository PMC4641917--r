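test_that("control state machine activates at 750 nm, toggles, and resets", {
  ev <- control_events(
    time = c(0, 1, 2, 3, 4, 5, 6, 7, 8),
    rst  = c(1, 0, 0, 0, 0, 1, 0, 0, 0),
    trig = c(0, 0, 1, 0, 1, 0, 0, 1, 0),
    ch1  = c(0, 1, 1, 1, 1, 0, 1, 1, 0),
    ch0  = c(0, 0, 0, 0, 0, 0, 1, 1, 0))
  st <- decode_control(ev)
  # first TRIG rise after reset: channel 2 (CH1:CH0 = 10) at 750 nm
  expect_equal(st$channel[1], 2L)
  expect_equal(st$wavelength[1], 750)
  # second rise toggles to 850 nm
  expect_equal(st$wavelength[2], 850)
  # RST high turns everything off ...
  off <- st[st$time == 5, ]
  expect_true(is.na(off$channel) && is.na(off$wavelength))
  # ... and the next rise starts again at 750 nm (now channel 3)
  last <- st[st$time == 7, ]
  expect_equal(last$channel, 3L)
  expect_equal(last$wavelength, 750)
})

test_that("after any reset the next activation is 750 nm, for every channel", {
  for (ch in 0:3) {
    ev <- control_events(
      time = c(0, 1, 2, 3, 4, 5),
      rst  = c(0, 0, 1, 0, 0, 0),
      trig = c(0, 1, 0, 0, 1, 0),    # rise, reset, rise
      ch1  = rep(ch %/% 2, 6),
      ch0  = rep(ch %% 2, 6))
    st <- decode_control(ev)
    acts <- st[!is.na(st$channel), ]
    expect_equal(acts$wavelength, c(750, 750))
    expect_equal(acts$channel, c(ch, ch))
  }
})

test_that("malformed control sequences are rejected", {
  expect_error(control_events(c(1, 0), 0, 0, 0, 0), "non-decreasing")
  expect_error(control_events(0, 2, 0, 0, 0), "exactly 0 or 1")
})

test_that("TDM schedule arithmetic and ordering follow the frame model", {
  s <- build_tdm_schedule(1, 4, 0.024, 0.0803)
  expect_equal(s$frame_period, 8 * 0.1043)
  expect_equal(s$sample_rate, 1 / 0.8344)
  # 750 nm precedes 850 nm within each channel; module-major, channel-minor
  expect_equal(s$slots$wavelength, rep(c(750, 850), 4))
  expect_equal(s$slots$channel, rep(0:3, each = 2))

  s1 <- build_tdm_schedule(1, 1, 0.01, 0.02)
  expect_equal(s1$frame_period, 2 * (0.01 + 0.02))  # two wavelengths

  s2 <- build_tdm_schedule(2, 4, 0.024, 0.0803)
  expect_equal(s2$frame_period, 2 * s$frame_period)  # shared converter

  expect_error(build_tdm_schedule(1, 0), "channels_per_module")
  expect_error(build_tdm_schedule(1, 4, dwell_time = 0), "dwell_time")
})

test_that("encoding a frame emits one TRIG rising edge per slot", {
  s <- build_tdm_schedule(1, 4)
  ev <- encode_control(s)
  rises <- sum(diff(c(0, ev$trig)) == 1 & ev$rst == 0)
  expect_equal(rises, 8)  # 4 channels x 2 wavelengths
  s1 <- build_tdm_schedule(1, 1)
  ev1 <- encode_control(s1)
  expect_equal(sum(diff(c(0, ev1$trig)) == 1 & ev1$rst == 0), 2)
})

test_that("decode(encode(schedule)) reproduces the slot timeline exactly", {
  set.seed(42)
  for (rep in 1:8) {
    s <- build_tdm_schedule(sample(1:2, 1), sample(1:4, 1),
                            runif(1, 0.005, 0.05), runif(1, 0.01, 0.1))
    n_frames <- sample(1:3, 1)
    tl <- fnirsim:::schedule_timeline(s, n_frames)
    dec <- decode_control(encode_control(s, n_frames))
    act <- dec[!is.na(dec$channel), ]
    expect_equal(act$time, tl$time)
    expect_equal(act$module_id, tl$module_id)
    expect_equal(act$channel, tl$channel)
    expect_equal(act$wavelength, tl$wavelength)
  }
})

test_that("packet CSV codec maps fields directly and round-trips losslessly", {
  p <- parse_packets("12.345,0,2,850,43210")
  expect_equal(p$timestamp, 12.345)
  expect_equal(p$module_id, 0L)
  expect_equal(p$channel, 2L)
  expect_equal(p$wavelength, 850)
  expect_equal(p$adc_code, 43210L)

  expect_error(parse_packets("a,b,c"), "line 1")
  expect_error(parse_packets("1.0,0,1,750,x"), "non-numeric")

  set.seed(7)
  n <- 1000
  pk <- data.frame(
    timestamp = round(sort(runif(n, 0, 1e4)), 6),
    module_id = sample(0:3, n, replace = TRUE),
    channel = sample(0:3, n, replace = TRUE),
    wavelength = sample(c(750, 850), n, replace = TRUE),
    adc_code = sample(0:65535, n, replace = TRUE))
  back <- parse_packets(write_packets(pk))
  expect_equal(back$timestamp, pk$timestamp)
  expect_equal(back$module_id, pk$module_id)
  expect_equal(back$channel, pk$channel)
  expect_equal(back$wavelength, pk$wavelength)
  expect_equal(back$adc_code, pk$adc_code)
})

test_that("packet writer and file round trip work through files", {
  pk <- data.frame(timestamp = c(0.1, 0.2), module_id = 0L, channel = c(0L, 1L),
                   wavelength = c(750, 850), adc_code = c(100L, 65535L))
  path <- withr::local_tempfile(fileext = ".csv")
  write_packets(pk, path)
  back <- parse_packets(path)
  expect_equal(back$adc_code, pk$adc_code)
  expect_equal(back$timestamp, pk$timestamp)
})
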