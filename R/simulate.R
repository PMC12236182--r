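#' Synthetic iEEG simulation configuration
#'
#' Parameters of the ground-truth simulator: a 1/f^alpha background, a
#' rhythmic delta-band (1-4 Hz) component that carries the planted
#' stimulation response (see [gen_delta_rhythm()]), interictal spikes, seizure-like events (SLEs)
#' whose termination phase carries delta-HFO phase-amplitude coupling,
#' and a sigmoidal delta-suppression dose-response to stimulation
#' amplitude. Amplitudes are in uV on the scale of rodent LFP recordings.
#'
#' The planted dose-response multiplies the delta component's amplitude
#' after a stimulation epoch by
#' `1 - (1 - delta_gain) * plogis((A - (threshold - 5)) / steepness)`:
#' a sigmoid whose midpoint sits half a 10-uA dose step below the
#' threshold, so the threshold amplitude itself already expresses the
#' full planted gain while the step below expresses essentially none.
#'
#' @param sample_rate Hz; default 10000, matching typical acquisition.
#'   Analyses only reach 512 Hz, so scaled-down rates (250-1250 Hz) are
#'   appropriate for fast runs.
#' @param background_alpha 1/f exponent of the broadband background.
#' @param background_rms Background RMS, uV.
#' @param delta_rms RMS of the rhythmic delta-band component, uV.
#' @param spike_rate Interictal spike rate, events/min.
#' @param spike_amplitude Spike peak amplitude, uV.
#' @param sle_duration SLE length, s.
#' @param sle_amplitude SLE body amplitude, uV.
#' @param sle_pac `list(f_l, f_h, chi)` for the termination-phase
#'   coupling; `chi` in [0, 1] is the modulation depth.
#' @param term_frac Fraction of the SLE occupied by the termination
#'   phase; default 0.25.
#' @param stim_threshold Planted dose-response threshold, uA.
#' @param delta_gain Post-stimulus delta amplitude multiplier above
#'   threshold, in (0, 1]; 1 plants no effect.
#' @param steepness Sigmoid steepness of the dose-response, uA.
#' @param seed Integer RNG seed.
#' @return A `sim_config` object.
#' @export
sim_config <- function(sample_rate = 10000, background_alpha = 1,
                       background_rms = 50, delta_rms = 80,
                       spike_rate = 6, spike_amplitude = 300,
                       sle_duration = 37, sle_amplitude = 400,
                       sle_pac = list(f_l = 1, f_h = 100, chi = 0.9),
                       term_frac = 0.25,
                       stim_threshold = 40, delta_gain = 0.5,
                       steepness = 1, seed = 1L) {
  stopifnot(sample_rate > 0, background_alpha >= 0, background_rms > 0,
            delta_rms >= 0, spike_rate >= 0, sle_duration > 0,
            sle_pac$chi >= 0, sle_pac$chi <= 1,
            delta_gain > 0, delta_gain <= 1, term_frac > 0, term_frac < 1)
  structure(list(sample_rate = sample_rate,
                 background_alpha = background_alpha,
                 background_rms = background_rms, delta_rms = delta_rms,
                 spike_rate = spike_rate,
                 spike_amplitude = spike_amplitude,
                 sle_duration = sle_duration,
                 sle_amplitude = sle_amplitude, sle_pac = sle_pac,
                 term_frac = term_frac, stim_threshold = stim_threshold,
                 delta_gain = delta_gain, steepness = steepness,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Gaussian 1/f^alpha background noise
#'
#' Spectral shaping of white Gaussian noise: Fourier amplitudes are
#' weighted by `f^(-alpha/2)` and the result rescaled to the target RMS
#' exactly. `alpha = 0` gives white noise; `alpha = 1` pink.
#'
#' @param n Number of samples.
#' @param sample_rate Hz.
#' @param alpha Spectral exponent (>= 0).
#' @param rms Target root-mean-square, uV.
#' @param seed RNG seed.
#' @return Numeric trace of length `n`, mean 0, RMS exactly `rms`.
#' @export
gen_background <- function(n, sample_rate, alpha = 1, rms = 50, seed = 1) {
  if (alpha < 0) stop("alpha must be >= 0", call. = FALSE)
  old <- saved_rng_state()
  set.seed(seed)
  on.exit(restore_rng(old), add = TRUE)
  shape_noise(stats::rnorm(n), sample_rate, function(f) f^(-alpha / 2), rms)
}

# weight(f) applied to the positive-frequency spectrum of x; DC zeroed.
shape_noise <- function(x, sample_rate, weight, rms) {
  n <- length(x)
  X <- stats::fft(x)
  f <- c(0, seq_len(n - 1)) * sample_rate / n
  f <- pmin(f, sample_rate - f)        # two-sided |frequency|
  w <- ifelse(f > 0, weight(f), 0)
  y <- Re(stats::fft(X * w, inverse = TRUE)) / n
  y <- y - mean(y)
  y * rms / sqrt(mean(y^2))
}

#' Rhythmic delta-band component
#'
#' The simulated hippocampal delta rhythm: a bank of amplitude-stable
#' sinusoidal oscillators spread across 1-4 Hz (default 1.25, 1.81,
#' 2.63, 3.81 Hz — separated by more than the Morlet bandwidth so their
#' wavelet magnitudes do not beat against each other), each with slow
#' (~0.1 Hz) fractional amplitude drift and a random phase. Amplitude
#' stability is the salient feature: the high-amplitude rhythmic slow
#' activity of kindled hippocampus has a steady envelope, which is what
#' makes baseline-z suppression statistics sensitive.
#'
#' @param n Samples.
#' @param sample_rate Hz.
#' @param rms Target RMS of the summed bank, uV.
#' @param seed RNG seed.
#' @param fbank Oscillator frequencies, Hz.
#' @param drift Fractional SD of the slow amplitude drift.
#' @return Numeric trace of length `n` with RMS exactly `rms`.
#' @export
gen_delta_rhythm <- function(n, sample_rate, rms, seed,
                             fbank = c(1.25, 1.81, 2.63, 3.81),
                             drift = 0.08) {
  old <- saved_rng_state()
  set.seed(seed)
  on.exit(restore_rng(old), add = TRUE)
  t <- (seq_len(n) - 1L) / sample_rate
  x <- numeric(n)
  for (fo in fbank) {
    am <- 1 + drift * slow_noise(n, sample_rate, 0.1)
    x <- x + am * sin(2 * pi * fo * t + stats::runif(1, 0, 2 * pi))
  }
  x * rms / sqrt(mean(x^2))
}

# unit-SD Gaussian noise low-passed to ~cutoff Hz (consumes RNG)
slow_noise <- function(n, sample_rate, cutoff) {
  w <- stats::rnorm(n)
  f <- c(0, seq_len(n - 1)) * sample_rate / n
  f <- pmin(f, sample_rate - f)
  y <- Re(stats::fft(stats::fft(w) * exp(-(f / cutoff)^2),
                     inverse = TRUE)) / n
  y <- y - mean(y)
  y / stats::sd(y)
}

#' Inject delta-HFO phase-amplitude coupling into a trace
#'
#' Inside `interval` adds a fast rhythm whose amplitude follows the phase
#' of a slow one, `gain * (1 + chi * sin(2 pi f_l t)) / 2 * sin(2 pi f_h t)`,
#' plus a visible slow component `0.5 * gain * sin(2 pi f_l t)`. `chi` is
#' the modulation depth: 0 plants no coupling (constant fast amplitude),
#' 1 full-depth coupling. The trace is untouched outside the interval.
#'
#' @param trace Numeric signal.
#' @param sample_rate Hz.
#' @param interval `c(start, end)` s, half-open, within the trace.
#' @param f_l,f_h Slow (phase) and fast (amplitude) frequencies, Hz;
#'   `f_h` must be below Nyquist.
#' @param chi Modulation depth in [0, 1].
#' @param gain Fast-rhythm peak amplitude, uV.
#' @return Modified trace.
#' @export
inject_pac <- function(trace, sample_rate, interval, f_l = 1, f_h = 100,
                       chi = 0.9, gain = 100) {
  if (f_h >= sample_rate / 2)
    stop("f_h must be below the Nyquist frequency", call. = FALSE)
  if (chi < 0 || chi > 1) stop("chi must be in [0, 1]", call. = FALSE)
  n <- length(trace)
  t <- (seq_len(n) - 1L) / sample_rate
  if (interval[1] < 0 || interval[2] > n / sample_rate + 1e-9)
    stop("interval outside trace", call. = FALSE)
  in_int <- t >= interval[1] & t < interval[2]
  tt <- t[in_int]
  trace[in_int] <- trace[in_int] +
    gain * (1 + chi * sin(2 * pi * f_l * tt)) / 2 * sin(2 * pi * f_h * tt) +
    0.5 * gain * sin(2 * pi * f_l * tt)
  trace
}

# biphasic sharp-wave template for interictal spikes (~80 ms)
spike_template <- function(sample_rate, amplitude) {
  t <- seq(-0.04, 0.04, by = 1 / sample_rate)
  amplitude * (-t / 0.012) * exp(0.5 - (t / 0.012)^2 / 2)
}

add_spikes <- function(trace, sample_rate, rate_per_min, amplitude,
                       intervals, seed) {
  if (rate_per_min <= 0 || !length(intervals)) return(trace)
  old <- saved_rng_state()
  set.seed(seed)
  on.exit(restore_rng(old), add = TRUE)
  tpl <- spike_template(sample_rate, amplitude)
  n <- length(trace)
  for (iv in intervals) {
    len <- iv[2] - iv[1]
    k <- stats::rpois(1, rate_per_min * len / 60)
    if (k == 0) next
    at <- sort(stats::runif(k, iv[1], iv[2]))
    for (t0 in at) {
      i0 <- round(t0 * sample_rate) + 1L
      i1 <- min(n, i0 + length(tpl) - 1L)
      trace[i0:i1] <- trace[i0:i1] + tpl[seq_len(i1 - i0 + 1L)]
    }
  }
  trace
}

#' Synthesize one seizure-like event
#'
#' Three electrographic phases: a low-voltage fast onset (first 10%), a
#' high-amplitude spike-wave body sweeping 8 to 3 Hz with superimposed
#' fast activity (middle), and a
#' termination phase (final `term_frac`) carrying delta-HFO
#' phase-amplitude coupling at the configured `(f_l, f_h, chi)`. The
#' morphology is deliberately schematic — shapes are config-exposed, not
#' fitted to any recording.
#'
#' @param config A [sim_config()].
#' @param onset SLE onset within the segment, s.
#' @param n Total segment length, samples; SLE must fit inside.
#' @return List: `trace` (numeric, zero outside the event — add it to a
#'   background), `annotations` tibble with the exact on/offset.
#' @export
gen_sle <- function(config, onset, n) {
  fs <- config$sample_rate
  dur <- config$sle_duration
  if (dur <= 0) stop("zero-duration SLE requested", call. = FALSE)
  if ((onset + dur) * fs > n)
    stop("SLE extends beyond the recording", call. = FALSE)
  t <- (seq_len(n) - 1L) / fs
  trace <- numeric(n)
  a <- config$sle_amplitude
  t_on <- onset + 0.1 * dur
  t_term <- onset + (1 - config$term_frac) * dur
  t_end <- onset + dur

  ph_onset <- t >= onset & t < t_on
  tt <- t[ph_onset] - onset
  trace[ph_onset] <- 0.35 * a * sin(2 * pi * 30 * tt) *
    (0.5 + 0.5 * tt / (t_on - onset))

  ph_body <- t >= t_on & t < t_term
  tt <- t[ph_body] - t_on
  body_len <- t_term - t_on
  f_inst <- 8 - 5 * tt / body_len               # 8 -> 3 Hz sweep
  phase <- 2 * pi * cumsum(f_inst) / fs
  # spike-wave morphology (sharpening harmonics) + superimposed fast
  # ictal activity: both give the discharge its high line-length
  trace[ph_body] <- a * (sin(phase) + 0.45 * sin(2 * phase) +
                           0.25 * sin(4 * phase)) +
    0.8 * a * sin(2 * pi * 30 * tt)

  trace <- inject_pac(trace, fs, c(t_term, t_end),
                      f_l = config$sle_pac$f_l, f_h = config$sle_pac$f_h,
                      chi = config$sle_pac$chi, gain = 0.8 * a)
  list(trace = trace,
       annotations = tibble::tibble(label = "sle", start = onset,
                                    end = t_end, payload = ""))
}

dose_gain <- function(amplitude, config) {
  1 - (1 - config$delta_gain) *
    stats::plogis((amplitude - (config$stim_threshold - 5)) /
                    config$steepness)
}

# cosine-ramped per-sample gain profile: g inside [start, end), 1 outside
gain_profile <- function(t, start, end, g, ramp = 1) {
  prof <- rep(1, length(t))
  core <- t >= start + ramp & t < end - ramp
  up <- t >= start & t < start + ramp
  down <- t >= end - ramp & t < end
  prof[core] <- g
  prof[up] <- 1 + (g - 1) * (1 - cos(pi * (t[up] - start) / ramp)) / 2
  prof[down] <- g + (1 - g) * (1 - cos(pi * (t[down] - (end - ramp)) / ramp)) / 2
  prof
}

#' Simulate an ascending-amplitude dose-response session
#'
#' Concatenated probe trials, each `[pre | stim | post]`: a pre-stimulation
#' baseline, a stimulation epoch filled with saturating artifact (so that
#' epoch masking is genuinely exercised) and annotated `"stim"`, and a
#' post interval in which the narrowband delta component is multiplied by
#' the planted sigmoidal dose gain — suppression appears only at and
#' above the planted threshold.
#'
#' @param config A [sim_config()].
#' @param amplitudes Ascending stimulation amplitudes, uA; default the
#'   conventional 10-uA steps 10-60.
#' @param pre_s,stim_s,post_s Per-trial interval lengths, s; defaults
#'   60 / 30 / 62.
#' @return List: `recording` (two-channel `pac_recording`; thalamic
#'   channel is a scaled copy), `truth` (list with `threshold`,
#'   `delta_gain`, and the per-trial `trials` tibble).
#' @export
gen_dose_response_session <- function(config, amplitudes = seq(10, 60, 10),
                                      pre_s = 60, stim_s = 30,
                                      post_s = 62) {
  if (any(diff(amplitudes) <= 0))
    stop("amplitudes must be ascending", call. = FALSE)
  fs <- config$sample_rate
  trial_s <- pre_s + stim_s + post_s
  total_s <- trial_s * length(amplitudes)
  n <- round(total_s * fs)
  t <- (seq_len(n) - 1L) / fs

  bg <- gen_background(n, fs, config$background_alpha,
                       config$background_rms, config$seed)
  delta <- gen_delta_rhythm(n, fs, config$delta_rms, config$seed + 1L)

  gain <- rep(1, n)
  ann <- empty_annotations()
  trials <- tibble::tibble(amplitude = amplitudes,
                           stim_start = NA_real_, stim_end = NA_real_,
                           applied_gain = NA_real_)
  for (i in seq_along(amplitudes)) {
    t0 <- (i - 1) * trial_s
    s0 <- t0 + pre_s
    s1 <- s0 + stim_s
    g <- dose_gain(amplitudes[i], config)
    gain <- gain * gain_profile(t, s1, s1 + post_s, g)
    ann <- dplyr::bind_rows(ann, tibble::tibble(
      label = "stim", start = s0, end = s1,
      payload = as.character(amplitudes[i])))
    trials$stim_start[i] <- s0
    trials$stim_end[i] <- s1
    trials$applied_gain[i] <- g
  }
  x <- bg + delta * gain
  x <- add_spikes(x, fs, config$spike_rate, config$spike_amplitude,
                  list(c(0, total_s)), config$seed + 2L)
  # stimulation epochs: amplifier-saturating artifact
  for (i in seq_len(nrow(ann))) {
    idx <- t >= ann$start[i] & t < ann$end[i]
    art <- 20 * config$background_rms *
      sign(sin(2 * pi * 7 * t[idx]) + 0.3)
    x[idx] <- art
  }
  rec <- new_recording(
    list(hippocampus = x, thalamus = 0.8 * x),
    fs, ann,
    list(seed = config$seed, kind = "dose_response_session"))
  list(recording = rec,
       truth = list(threshold = config$stim_threshold,
                    delta_gain = config$delta_gain, trials = trials))
}

#' Split a simulated session into probe trials
#'
#' Uses the `"stim"` annotations of a session recording to build one
#' [probe_trial()] per stimulation epoch, each on its own recording
#' segment.
#'
#' @param rec A session `pac_recording` (e.g. from
#'   [gen_dose_response_session()]).
#' @param channel Channel to analyse; default the first.
#' @param post_s Post-interval length, s; default 60 starting 1 s after
#'   the epoch.
#' @return List of `probe_trial` objects, in epoch order.
#' @export
session_probe_trials <- function(rec, channel = NULL, post_s = 60) {
  ann <- annotations(rec)
  stim <- ann[ann$label == "stim", ]
  stim <- stim[order(stim$start), ]
  fs <- sample_rate(rec)
  chans <- setdiff(names(rec), "time")
  channel <- channel %||% chans[1]
  x <- rec[[channel]]
  dur <- length(x) / fs
  purrr::map(seq_len(nrow(stim)), function(i) {
    seg_start <- if (i == 1) 0 else stim$end[i - 1] + post_s + 1
    seg_start <- max(0, min(seg_start, stim$start[i] - 1))
    seg_end <- min(dur, stim$end[i] + post_s + 2)
    i0 <- round(seg_start * fs) + 1L
    i1 <- round(seg_end * fs)
    probe_trial(x[i0:i1],
                epoch = c(stim$start[i], stim$end[i]) - seg_start,
                amplitude = as.numeric(stim$payload[i]),
                sample_rate = fs)
  })
}

#' Simulate an evoked-seizure trial
#'
#' Timeline: a quiet lead-in, an optional therapeutic stimulation epoch
#' that ends 6 s after the evoked (kindling) stimulus marker, the evoked
#' stimulus, and either a full seizure-like event (control) or a
#' suppressed, quiescent response (`with_depacer = TRUE`, which also
#' reduces the interictal spike rate). Stimulation-epoch samples are
#' artifact-filled and annotated so the emitted mask flags them invalid.
#' The therapeutic epoch defaults to 60 s; the full 15-min protocol is a
#' parameter away (`pre_stim_s = 900`).
#'
#' @param config A [sim_config()].
#' @param with_depacer Logical: apply the therapeutic stimulus?
#' @param lead_s Quiet lead-in before any stimulation, s; default 30.
#' @param pre_stim_s Therapeutic stimulation length, s; default 60.
#' @param tail_s Recording continued after the SLE window, s; default 20.
#' @return List: `recording` (`pac_recording` with `"stim"`, `"evoked"`
#'   and (control) `"sle"` annotations), `truth` (list with
#'   `evoked_time`, `sle_duration` — 0 under suppression).
#' @export
gen_evoked_trial <- function(config, with_depacer = FALSE, lead_s = 30,
                             pre_stim_s = 60, tail_s = 20) {
  fs <- config$sample_rate
  evoked_time <- lead_s + pre_stim_s - 6
  total_s <- lead_s + pre_stim_s + config$sle_duration + tail_s
  n <- round(total_s * fs)
  t <- (seq_len(n) - 1L) / fs

  bg <- gen_background(n, fs, config$background_alpha,
                       config$background_rms, config$seed)
  delta <- gen_delta_rhythm(n, fs, config$delta_rms, config$seed + 1L)
  x <- bg + delta
  ann <- tibble::tibble(label = "evoked", start = evoked_time,
                        end = evoked_time + 2, payload = "")
  spike_rate <- config$spike_rate * (if (with_depacer) 0.2 else 1)
  x <- add_spikes(x, fs, spike_rate, config$spike_amplitude,
                  list(c(0, evoked_time)), config$seed + 2L)
  sle_duration <- 0
  if (!with_depacer) {
    sle <- gen_sle(config, onset = evoked_time + 0.5, n = n)
    x <- x + sle$trace
    ann <- dplyr::bind_rows(ann, sle$annotations)
    sle_duration <- config$sle_duration
  }
  if (with_depacer) {
    s0 <- lead_s
    s1 <- lead_s + pre_stim_s
    idx <- t >= s0 & t < s1
    x[idx] <- 20 * config$background_rms *
      sign(sin(2 * pi * 7 * t[idx]) + 0.3)
    ann <- dplyr::bind_rows(
      tibble::tibble(label = "stim", start = s0, end = s1,
                     payload = "depacer"), ann)
  }
  rec <- new_recording(
    list(hippocampus = x, thalamus = 0.8 * x), fs, ann,
    list(seed = config$seed, kind = "evoked_trial",
         with_depacer = with_depacer))
  list(recording = rec,
       truth = list(evoked_time = evoked_time,
                    sle_duration = sle_duration))
}
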