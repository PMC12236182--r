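fs_b <- 250

make_probe <- function(gain_post, seed, amplitude = 40, fs = fs_b) {
  dur <- 152
  n <- dur * fs
  times <- (seq_len(n) - 1) / fs
  bg <- gen_background(n, fs, 1, 50, seed)
  d <- gen_delta_rhythm(n, fs, 80, seed + 100)
  g <- ifelse(times >= 91 & times < 151, gain_post, 1)
  x <- bg + d * g
  art <- times >= 60 & times < 90
  x[art] <- 1000 * sign(sin(2 * pi * 7 * times[art]) + 0.3)
  probe_trial(x, epoch = c(60, 90), amplitude = amplitude,
              sample_rate = fs)
}

test_that("no planted change yields a near-zero z summary", {
  z <- delta_change(make_probe(1, seed = 21))
  expect_lt(abs(z), 1)
})

test_that("a 50% delta reduction yields clear negative suppression", {
  z <- delta_change(make_probe(0.5, seed = 22))
  expect_lt(z, -1.96)
})

test_that("stimulation-epoch artifact is neutralized by masking", {
  tr <- make_probe(1, seed = 23)
  z_masked <- delta_change(tr)
  # mis-declare the epoch so the artifact-filled span enters the
  # evaluation interval unmasked
  tr_unmasked <- tr
  tr_unmasked$epoch <- c(0.25, 0.5)
  tr_unmasked$pre <- c(2, 59)
  tr_unmasked$post <- c(59, 120)
  z_unmasked <- delta_change(tr_unmasked)
  expect_gt(abs(z_unmasked), 5 * abs(z_masked))
})

test_that("short baselines are rejected", {
  tr <- make_probe(1, seed = 24)
  tr$pre <- c(50, 60)
  expect_error(delta_change(tr), "baseline")
})

test_that("dose series detects the smallest suppressed amplitude", {
  cfg <- sim_config(sample_rate = fs_b, seed = 31)
  ses <- gen_dose_response_session(cfg)
  trials <- session_probe_trials(ses$recording)
  res <- run_dose_series(trials)
  expect_s3_class(res, "dose_response")
  expect_equal(res$threshold, ses$truth$threshold)
  expect_true(all(diff(res$table$amplitude) > 0))
  # detection is deterministic given the recording
  expect_equal(run_dose_series(trials)$table$delta_z, res$table$delta_z)
  # tidy/glance contracts
  expect_named(tidy(res), c("amplitude", "delta_z", "suppressed"))
  expect_equal(glance(res)$threshold, res$threshold)
  # relaxing the criterion can only lower (or keep) the threshold
  thr_seq <- vapply(c(-3, -1.96, -1, -0.5), function(cr) {
    r <- run_dose_series(trials, criterion = cr)
    if (is.na(r$threshold)) Inf else r$threshold
  }, numeric(1))
  expect_true(all(diff(thr_seq) <= 0))
})

test_that("an all-subthreshold series reports no threshold", {
  cfg <- sim_config(sample_rate = fs_b, delta_gain = 1, seed = 32)
  ses <- gen_dose_response_session(cfg)
  res <- run_dose_series(session_probe_trials(ses$recording))
  expect_true(is.na(res$threshold))
})

test_that("dose series validates its inputs", {
  cfg <- sim_config(sample_rate = fs_b, seed = 33)
  trials <- session_probe_trials(gen_dose_response_session(cfg)$recording)
  expect_error(run_dose_series(trials[1]), "at least 2")
  expect_error(run_dose_series(rev(trials)), "increasing")
})

test_that("paired Wilcoxon matches the exact enumeration oracle", {
  set.seed(41)
  for (n in c(6, 8, 10)) {
    for (rep in 1:5) {
      a <- rnorm(n, 1)
      b <- rnorm(n)
      res <- paired_group_test(a, b)
      expect_equal(res$p_value, wilcoxon_exact_oracle(a, b),
                   tolerance = 1e-12)
    }
  }
  # constant shift, n = 19: every difference positive, so the exact
  # two-sided p is twice the point mass of the extreme statistic
  a <- sort(rnorm(19))
  res <- paired_group_test(a + 1, a)
  expect_equal(res$method, "exact")
  expect_equal(res$p_value, 2 / 2^19, tolerance = 1e-12)
  expect_equal(res$statistic, 19 * 20 / 2)
  # tied |differences| still get an exact (midrank) null distribution
  a2 <- c(1, 2, 3, 4, 5, 6)
  b2 <- c(0, 3, 1, 2, 4, 4)
  expect_equal(paired_group_test(a2, b2)$p_value,
               wilcoxon_exact_oracle(a2, b2), tolerance = 1e-12)
})

test_that("paired test reports means with SEM and rejects degenerate input", {
  a <- c(37, 40, 35, 39, 36, 38)
  res <- paired_group_test(a, rep(0, 6))
  expect_equal(res$mean_a, mean(a))
  expect_equal(res$sem_a, sd(a) / sqrt(6))
  expect_equal(res$sem_b, 0)
  expect_error(paired_group_test(a, a), "zero")
  expect_error(paired_group_test(a, a[1:3]), "paired")
  expect_error(paired_group_test(a[1:4], rep(0, 4)), "n >= 5")
})

test_that("evoked afterdischarge duration recovers the programmed length", {
  for (s in c(51, 52, 53)) {
    cfg <- sim_config(sample_rate = 500, seed = s)
    ev <- gen_evoked_trial(cfg, with_depacer = FALSE)
    d <- evoked_duration(ev$recording, ev$truth$evoked_time)
    expect_lt(abs(d - cfg$sle_duration), 2)
  }
})

test_that("a quiescent post-stimulus recording scores zero duration", {
  cfg <- sim_config(sample_rate = 500, seed = 54)
  ev <- gen_evoked_trial(cfg, with_depacer = TRUE)
  expect_equal(evoked_duration(ev$recording, ev$truth$evoked_time), 0)
})

test_that("duration is invariant to overall signal gain", {
  cfg <- sim_config(sample_rate = 500, seed = 55)
  ev <- gen_evoked_trial(cfg, with_depacer = FALSE)
  x <- ev$recording$hippocampus
  d1 <- evoked_duration(x, ev$truth$evoked_time, sample_rate = 500)
  d2 <- evoked_duration(2 * x, ev$truth$evoked_time, sample_rate = 500)
  expect_equal(d1, d2)
  expect_error(evoked_duration(x, 1e6, sample_rate = 500), "outside")
  expect_error(evoked_duration(x[1:(500 * 11)], 5, sample_rate = 500),
               "10 s")
})
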