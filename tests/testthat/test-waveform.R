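test_that("envelope evaluates both modes at the cardinal phases", {
  expect_equal(envelope_at(pi / 2, 40), 40)
  expect_equal(envelope_at(0, 40), 0)
  # direct evaluation of the two formulas at phase 3*pi/2
  expect_equal(envelope_at(3 * pi / 2, 40, "rectified_sine"), 0)
  expect_equal(envelope_at(3 * pi / 2, 40, "signed_sine"), -40)
  ph <- seq(0, 2 * pi, length.out = 97)
  expect_true(all(abs(envelope_at(ph, 40)) <= 40))
  expect_true(all(envelope_at(ph, 40, "rectified_sine") >= 0))
})

test_that("zero dither gives an exactly periodic train on [0, duration)", {
  spec <- stim_spec(dither_spread = 0, duration = 1)
  p <- sample_pulse_times(spec)
  # first pulse at the first interval, half-open upper boundary excluded
  expect_equal(nrow(p), 99)
  expect_equal(p$onset_time, (1:99) / 100)
  expect_true(all(p$instantaneous_frequency == 100))
})

test_that("dithered draws recover the configured mean and spread", {
  spec <- stim_spec(duration = 120)
  p <- sample_pulse_times(spec)
  expect_gt(nrow(p), 1e4)
  expect_true(all(diff(p$onset_time) > 0))
  # gaps equal the reciprocal of the earlier pulse's drawn frequency
  expect_equal(diff(p$onset_time),
               1 / p$instantaneous_frequency[-nrow(p)], tolerance = 1e-8)
  oracle <- truncnorm_moments(100, 10, 50)
  se <- oracle["sd"] / sqrt(nrow(p))
  expect_lt(abs(mean(p$instantaneous_frequency) - oracle["mean"]), 3 * se)
  expect_lt(abs(sd(p$instantaneous_frequency) - oracle["sd"]), 0.5)
  # truncation floor respected
  expect_true(all(p$instantaneous_frequency >= 50))
})

test_that("biphasic pulse blocks are charge-balanced with positive phase first", {
  blk <- render_biphasic_pulse(40, 1, 10000)
  expect_equal(blk, c(rep(40, 5), rep(-40, 5)))
  expect_equal(sum(blk), 0)
  expect_equal(render_biphasic_pulse(0, 1, 10000), rep(0, 10))
  for (a in c(-17.5, 3, 120)) {
    expect_equal(sum(render_biphasic_pulse(a, 2, 5000)), 0)
  }
  # odd sample count cannot balance
  expect_error(render_biphasic_pulse(40, 0.5, 10000), "even")
})

test_that("depacer waveform follows the sinusoidal envelope", {
  spec <- stim_spec(duration = 2, seed = 5)
  w <- generate_depacer(spec)
  expect_equal(nrow(w), 20000)
  expect_equal(sum(w$current), 0)          # charge balance
  expect_lte(max(abs(w$current)), 40)
  p <- pulse_events(w)
  # least-squares fit of per-pulse amplitudes to A*sin(2 pi f_l t + phi)
  fit <- lm(amplitude ~ sin(2 * pi * onset_time) + cos(2 * pi * onset_time)
            - 1, data = p)
  A <- sqrt(sum(coef(fit)^2))
  phi <- atan2(coef(fit)[2], coef(fit)[1])
  expect_lt(abs(A - 40) / 40, 0.02)
  expect_lt(abs(phi), 0.05)
  # half-period antisymmetry at zero dither: a(t) = -a(t + 0.5), i.e.
  # pulse k against pulse k + 50 at the exact 100 Hz spacing
  w0 <- generate_depacer(stim_spec(dither_spread = 0, duration = 2))
  a <- pulse_events(w0)$amplitude
  expect_equal(a[1:100], -a[51:150], tolerance = 1e-6)
})

test_that("zero peak amplitude produces an all-zero waveform", {
  w <- generate_depacer(stim_spec(a0 = 0, duration = 1))
  expect_true(all(w$current == 0))
})

test_that("identical spec and seed reproduce the waveform exactly", {
  spec <- stim_spec(duration = 3, seed = 42)
  expect_identical(generate_depacer(spec), generate_depacer(spec))
})

test_that("mono-rhythmic trains have floor(duration*f) constant pulses", {
  hfs <- generate_monorhythmic(stim_spec(waveform_kind = "hfs",
                                         dither_spread = 0, duration = 1))
  expect_equal(nrow(pulse_events(hfs)), 100)
  expect_equal(var(abs(pulse_events(hfs)$amplitude)), 0)
  lfs <- generate_monorhythmic(stim_spec(waveform_kind = "lfs",
                                         dither_spread = 0, duration = 10))
  expect_equal(nrow(pulse_events(lfs)), 10)
  expect_equal(sum(lfs$current), 0)
})

test_that("zero-dither constant-envelope depacer aligns with the hfs train", {
  # hfs pulses start at t = 0, the dithered generator after one interval:
  # the trains coincide up to that one-interval shift
  dep <- generate_depacer(stim_spec(dither_spread = 0, duration = 1,
                                    envelope_mode = "constant"))
  hfs <- generate_monorhythmic(stim_spec(waveform_kind = "hfs",
                                         dither_spread = 0, duration = 1))
  shift <- 100  # samples in one 10-ms interval at 10 kHz
  n <- nrow(dep)
  expect_true(all(dep$current[1:shift] == 0))
  expect_equal(dep$current[(shift + 1):n], hfs$current[1:(n - shift)])
})

test_that("kindling train is 120 monophasic 0.5-ms pulses at 60 Hz", {
  k <- generate_kindling_train(100)
  p <- pulse_events(k)
  expect_equal(nrow(p), 120)
  expect_true(all(k$current >= 0))              # monophasic
  expect_equal(sum(k$current > 0), 120 * 5)     # 0.5 ms = 5 samples each
  expect_equal(nrow(k), 20000)
  z <- suppressWarnings(generate_kindling_train(0))
  expect_true(all(z$current == 0))
  expect_equal(nrow(z), 20000)
  expect_warning(generate_kindling_train(200), "outside")
})

test_that("waveform text export round-trips bit-exactly", {
  w <- generate_depacer(stim_spec(duration = 1, seed = 9))
  f1 <- withr::local_tempfile(fileext = ".txt")
  f2 <- withr::local_tempfile(fileext = ".txt")
  export_waveform(w, f1)
  lines <- readLines(f1)
  body <- lines[!startsWith(lines, "#")]
  expect_length(body, 10000)                     # 1 s at 10 kHz
  expect_match(grep("seed", lines, value = TRUE), "seed: 9")
  w2 <- read_waveform(f1)
  export_waveform(w2, f2)
  l2 <- readLines(f2)
  expect_identical(body, l2[!startsWith(l2, "#")])
  expect_identical(w2$current, w$current)
  expect_equal(attr(w2, "spec")$seed, 9L)
})

test_that("invalid stimulus specs are rejected", {
  expect_error(stim_spec(f_l = 0), "f_l")
  expect_error(stim_spec(pulse_width = 0.123), "whole number")
  # pulses would overlap at the mean rate
  expect_error(stim_spec(f_h = 900, pulse_width = 2), "overlap")
  expect_error(generate_monorhythmic(stim_spec()), "lfs")
  expect_error(generate_depacer(stim_spec(waveform_kind = "hfs")),
               "depacer")
})
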