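fs_p <- 512

test_that("phase extraction follows the sine convention and wraps", {
  t <- seq(0, 6, by = 1 / fs_p)
  f0 <- 8
  s <- morlet_cwt(sin(2 * pi * f0 * t), fs_p,
                  wavelet_params(frequency_grid = c(4, 8, 16)))
  ph <- extract_phase(s, f0)
  expect_true(all(ph > -pi & ph <= pi + 1e-12))
  mid <- !s$coi[, 2]
  # maxima of sin sit at phase pi/2
  imax <- which(mid & abs(sin(2 * pi * f0 * t) - 1) < 1e-6)
  expect_lt(max(abs(ph[imax] - pi / 2)), 0.05)
  # unwrapped phase advances by 2 pi f per second
  dph <- diff(ph[mid])
  dph <- dph[abs(dph) < pi]
  expect_equal(mean(dph) * fs_p / (2 * pi), f0, tolerance = 0.01)
  # cosine convention: conjugating coefficients negates the phase
  s2 <- s
  s2$coefficients <- Conj(s2$coefficients)
  pc <- extract_phase(s, f0, convention = "cosine")
  pc2 <- extract_phase(s2, f0, convention = "cosine")
  ok <- abs(pc) < 3  # avoid the branch point at +pi
  expect_equal(pc2[ok], -pc[ok], tolerance = 1e-12)
  expect_error(extract_phase(s, 9), "not in the scalogram grid")
})

test_that("amplitude extraction is the non-negative modulus and scales", {
  t <- seq(0, 4, by = 1 / fs_p)
  wp <- wavelet_params(frequency_grid = c(8, 16))
  z <- morlet_cwt(numeric(length(t)), fs_p, wp)
  expect_true(all(extract_amplitude(z, 8) == 0))
  for (phi0 in c(0, 1.2)) {
    s1 <- morlet_cwt(sin(2 * pi * 8 * t + phi0), fs_p, wp)
    s2 <- morlet_cwt(2 * sin(2 * pi * 8 * t + phi0), fs_p, wp)
    expect_true(all(extract_amplitude(s1, 8) >= 0))
    expect_equal(extract_amplitude(s2, 8), 2 * extract_amplitude(s1, 8),
                 tolerance = 1e-12)
  }
  # amplitude is invariant to the tone's initial phase (away from edges)
  sA <- morlet_cwt(sin(2 * pi * 8 * t), fs_p, wp)
  sB <- morlet_cwt(sin(2 * pi * 8 * t + 2), fs_p, wp)
  mid <- !sA$coi[, 1]
  expect_equal(mean(extract_amplitude(sA, 8)[mid]),
               mean(extract_amplitude(sB, 8)[mid]), tolerance = 1e-3)
})

test_that("modulation index hits its analytic extremes", {
  set.seed(7)
  ph <- runif(2e4, -pi, pi)
  expect_equal(modulation_index(ph, rep(2.5, 2e4)), 0)
  # one full 20-degree bin: (0, 2*pi/18] is exactly the bin above zero
  onebin <- as.numeric(ph > 0 & ph <= 2 * pi / 18)
  expect_equal(modulation_index(ph, onebin), 1)
  expect_error(modulation_index(ph, rep(0, 2e4)), "all-zero")
})

test_that("modulation index matches the brute-force histogram oracle", {
  set.seed(11)
  for (chi in c(0.2, 0.5, 0.8)) {
    ph <- runif(5e3, -pi, pi)
    amp <- 1 + chi * sin(ph)
    mi <- modulation_index(ph, amp)
    expect_equal(mi, mi_oracle(ph, amp), tolerance = 1e-12)
    expect_gt(mi, 0)
    expect_lt(mi, 1)
  }
  # irregular amplitudes too
  ph <- runif(3e3, -pi, pi)
  amp <- rexp(3e3) * (1 + 0.4 * cos(ph))
  expect_equal(modulation_index(ph, amp), mi_oracle(ph, amp),
               tolerance = 1e-12)
})

test_that("MI is invariant to amplitude scale and bin-aligned rotation", {
  set.seed(3)
  ph <- runif(1e4, -pi, pi)
  amp <- 1 + 0.6 * sin(ph)
  mi <- modulation_index(ph, amp)
  for (c0 in c(0.01, 7, 1e4)) {
    expect_equal(modulation_index(ph, c0 * amp), mi, tolerance = 1e-12)
  }
  # rotation by whole bins leaves MI exactly unchanged
  expect_equal(modulation_index(ph + 3 * (2 * pi / 18), amp), mi,
               tolerance = 1e-12)
  # arbitrary rotation: unchanged up to bin-quantization jitter
  expect_equal(modulation_index(ph + 0.7, amp), mi, tolerance = 0.02)
})

test_that("MI grows with modulation depth", {
  set.seed(5)
  ph <- runif(2e4, -pi, pi)
  mis <- vapply(seq(0, 1, by = 0.1), function(chi)
    modulation_index(ph, 1 + chi * sin(ph)), numeric(1))
  expect_true(all(diff(mis) >= 0))
  expect_equal(mis[1], 0, tolerance = 1e-3)
})

test_that("comodulogram peaks at the injected coupling cell", {
  dur <- 20
  fs <- 1250
  bg <- gen_background(dur * fs, fs, 1, 50, 3)
  x <- inject_pac(bg, fs, c(0, dur), f_l = 1, f_h = 100, chi = 0.9,
                  gain = 150)
  p <- comodulogram_params()
  expect_equal(p$n_phase_bins, 18)       # 20-degree bins
  expect_equal(range(p$phase_freqs), c(1, 32))
  expect_equal(range(p$amp_freqs), c(32, 512))
  grid <- sort(union(p$phase_freqs, p$amp_freqs))
  s <- morlet_cwt(x, fs, wavelet_params(frequency_grid = grid))
  cm <- comodulogram(s, p)
  pool <- pool_comodulogram(cm)
  best <- pool[which.max(pool$mi), ]
  expect_equal(best$f_phase, p$phase_freqs[which.min(abs(p$phase_freqs - 1))])
  expect_equal(best$f_amp, p$amp_freqs[which.min(abs(p$amp_freqs - 100))])
})

test_that("windowed comodulogram equals the naive full recompute", {
  fs <- 256
  x <- inject_pac(gen_background(12 * fs, fs, 1, 30, 8), fs, c(0, 12),
                  f_l = 2, f_h = 40, chi = 0.7, gain = 80)
  p <- comodulogram_params(phase_freqs = c(1, 2, 4),
                           amp_freqs = c(32, 40, 64),
                           window = 4, stride = 2)
  s <- morlet_cwt(x, fs, wavelet_params(frequency_grid = c(1, 2, 4, 32,
                                                           40, 64)))
  cm <- comodulogram(s, p)
  for (r in seq_len(nrow(cm))) {
    w0 <- cm$window_start[r]
    idx <- which(s$times >= w0 & s$times < w0 + 4)
    mi_naive <- mi_oracle(extract_phase(s, cm$f_phase[r])[idx],
                          extract_amplitude(s, cm$f_amp[r])[idx])
    expect_lt(abs(cm$mi[r] - mi_naive), 1e-12)
  }
})

test_that("fully masked windows are omitted, not NA-filled", {
  fs <- 256
  x <- gen_background(12 * fs, fs, 1, 30, 2)
  mask <- rep(TRUE, length(x))
  times <- (seq_along(x) - 1) / fs
  mask[times >= 4 & times < 8] <- FALSE
  p <- comodulogram_params(phase_freqs = c(1, 2), amp_freqs = c(32, 64),
                           window = 4, stride = 4)
  s <- morlet_cwt(x, fs, wavelet_params(frequency_grid = c(1, 2, 32, 64)))
  cm <- comodulogram(s, p, mask = mask)
  expect_false(4 %in% cm$window_start)
  expect_true(all(c(0, 8) %in% cm$window_start))
  expect_false(anyNA(cm$mi))
})

test_that("white noise stays below the surrogate significance floor", {
  fs <- 256
  set.seed(13)
  below <- vapply(1:10, function(i) {
    x <- rnorm(10 * fs)
    s <- morlet_cwt(x, fs, wavelet_params(frequency_grid = c(2, 40)))
    ph <- extract_phase(s, 2)
    am <- extract_amplitude(s, 40)
    modulation_index(ph, am) <
      surrogate_threshold(ph, am, fs, n_surrogates = 99, seed = i)
  }, logical(1))
  expect_gte(mean(below), 0.9)
})

test_that("strong coupling exceeds the surrogate floor deterministically", {
  # the modulating phase must drift (as real rhythms do) for circular
  # shifts to destroy alignment; a strictly periodic modulator would be
  # realigned by shifts near multiples of its period
  fs <- 512
  set.seed(6)
  n <- 10 * fs
  finst <- 2 + 0.8 * as.numeric(scale(cumsum(rnorm(n))))
  ph <- (2 * pi * cumsum(finst) / fs) %% (2 * pi) - pi
  am <- 1 + 0.9 * sin(ph) + 0.05 * rnorm(n)
  am <- pmax(am, 0)
  thr1 <- surrogate_threshold(ph, am, fs, n_surrogates = 49, seed = 7)
  thr2 <- surrogate_threshold(ph, am, fs, n_surrogates = 49, seed = 7)
  expect_identical(thr1, thr2)            # fixed seed, fixed threshold
  expect_gt(modulation_index(ph, am), thr1)
  expect_error(surrogate_threshold(ph[1:200], am[1:200], fs), "2 s")
  expect_error(surrogate_threshold(ph, am, fs, n_surrogates = 10), ">= 19")
})

test_that("comodulogram parameter contracts hold", {
  expect_error(comodulogram_params(window = 2), "4 cycles")
  expect_error(comodulogram_params(n_phase_bins = 2), ">= 4")
  # window of 4 s covers at least 4 cycles at the 1 Hz phase floor
  p <- comodulogram_params()
  expect_gte(p$window * min(p$phase_freqs), 4)
})
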