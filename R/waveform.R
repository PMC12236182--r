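#' Envelope value at a given low-frequency phase
#'
#' The amplitude assigned to a pulse fired at low-rhythm phase `phase`.
#' `signed_sine` implements `a0 * sin(phase)` — the pulse polarity flips on
#' the negative half-cycle. `rectified_sine` keeps amplitude non-negative,
#' `a0 * (1 + sin(phase)) / 2`. `constant` returns `a0` regardless of phase.
#'
#' @param phase Phase of the low-frequency rhythm, radians. Vectorized.
#' @param a0 Peak amplitude, uA.
#' @param mode `"signed_sine"`, `"rectified_sine"` or `"constant"`.
#' @return Signed amplitude(s) in `[-a0, a0]`.
#' @examples
#' envelope_at(pi / 2, 40)            # 40
#' envelope_at(3 * pi / 2, 40, "rectified_sine")  # 0
#' @export
envelope_at <- function(phase, a0,
                        mode = c("signed_sine", "rectified_sine",
                                 "constant")) {
  mode <- match.arg(mode)
  switch(mode,
         signed_sine    = a0 * sin(phase),
         rectified_sine = a0 * (1 + sin(phase)) / 2,
         constant       = rep_len(a0, length(phase)))
}

#' Draw dithered pulse times for a high-frequency train
#'
#' Sequential per-pulse instantaneous frequencies are drawn from
#' `Normal(f_h, dither_spread^2)`, truncated below at `f_h / 2` by
#' redrawing (keeps inter-pulse intervals within one octave of the mean;
#' at the default spread the rejected mass is ~ 3e-7). Each inter-pulse
#' interval is the reciprocal of its draw; onsets are the cumulative sums,
#' so the first pulse sits at the first drawn interval and generation is
#' half-open on `[0, duration)`.
#'
#' @param spec A [stim_spec()].
#' @param seed Seed for the draws; defaults to `spec$seed`.
#' @return A tibble of pulse events: `onset_time` (s, strictly increasing),
#'   `instantaneous_frequency` (Hz, the draw that produced the following
#'   interval) and `amplitude` (filled with `NA`; set by the waveform
#'   generators from the envelope).
#' @export
sample_pulse_times <- function(spec, seed = spec$seed) {
  validate_stim_spec(spec)
  f_h <- spec$f_h
  spread <- spec$dither_spread
  if (f_h / 2 <= 0) stop("f_h / 2 must be positive", call. = FALSE)
  old <- saved_rng_state()
  set.seed(seed)
  on.exit(restore_rng(old), add = TRUE)

  if (spread == 0) {
    n <- ceiling(spec$duration * f_h) + 1L
    freqs <- rep(f_h, n)
  } else {
    # draw in blocks, redraw sub-f_h/2 values; error on pathological spread
    n_expect <- ceiling(spec$duration * (f_h + 3 * spread)) + 10L
    freqs <- stats::rnorm(n_expect, f_h, spread)
    bad <- which(freqs < f_h / 2)
    tries <- 0L
    while (length(bad) > 0) {
      redraw <- stats::rnorm(length(bad), f_h, spread)
      ok <- redraw >= f_h / 2
      freqs[bad[ok]] <- redraw[ok]
      bad <- bad[!ok]
      tries <- tries + 1L
      if (tries > 1000L)
        stop("truncation rejected > 1000 consecutive draws; ",
             "dither_spread is pathological relative to f_h", call. = FALSE)
    }
  }
  onsets <- cumsum(1 / freqs)
  keep <- onsets < spec$duration
  # guarantee coverage of the full duration even for slow draws
  while (all(keep)) {
    extra <- if (spread == 0) rep(f_h, 16L) else {
      e <- stats::rnorm(16L, f_h, spread)
      e[e < f_h / 2] <- f_h
      e
    }
    freqs <- c(freqs, extra)
    onsets <- cumsum(1 / freqs)
    keep <- onsets < spec$duration
  }
  idx <- which(keep)
  tibble::tibble(
    onset_time = onsets[idx],
    # each pulse records the draw producing the interval that FOLLOWS it
    # (the first draw covers the virtual pulse at t = 0)
    instantaneous_frequency = freqs[idx + 1L],
    amplitude = NA_real_)
}

saved_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Render one charge-balanced biphasic square pulse
#'
#' Positive phase first, equal halves, zero inter-phase gap: the block sums
#' to zero exactly for any amplitude.
#'
#' @param amplitude Signed amplitude, uA (the leading phase carries its
#'   sign; the trailing phase is its negation).
#' @param pulse_width Total pulse duration, ms; must span an even number
#'   (>= 2) of samples so the two phases can balance.
#' @param sample_rate Hz.
#' @return Numeric vector of `pulse_width * sample_rate / 1000` samples.
#' @examples
#' render_biphasic_pulse(40, 1, 10000)  # five +40 then five -40
#' @export
render_biphasic_pulse <- function(amplitude, pulse_width, sample_rate) {
  n <- pulse_width * sample_rate / 1000
  if (abs(n - round(n)) > 1e-9)
    stop("pulse_width must span a whole number of samples", call. = FALSE)
  n <- as.integer(round(n))
  if (n < 2L || n %% 2L != 0L)
    stop("biphasic pulse needs an even sample count >= 2 ",
         "(cannot charge-balance ", n, " samples)", call. = FALSE)
  c(rep(amplitude, n %/% 2L), rep(-amplitude, n %/% 2L))
}

# Place pulse blocks onto a zeroed sample grid. Errors on overlap.
place_pulses <- function(pulses, spec, block_fun) {
  n <- as.integer(round(spec$duration * spec$sample_rate))
  samples <- numeric(n)
  idx <- as.integer(round(pulses$onset_time * spec$sample_rate)) + 1L
  pw <- length(block_fun(0))
  last_end <- 0L
  for (i in seq_len(nrow(pulses))) {
    s <- idx[i]
    e <- s + pw - 1L
    if (s <= last_end)
      stop("pulse blocks overlap at t = ", pulses$onset_time[i],
           " s; reduce pulse_width or the pulse rate", call. = FALSE)
    if (e > n) break  # block would run past the end of the grid
    samples[s:e] <- block_fun(pulses$amplitude[i])
    last_end <- e
  }
  samples
}

new_waveform <- function(samples, pulses, spec) {
  n <- length(samples)
  w <- tibble::tibble(
    time = (seq_len(n) - 1L) / spec$sample_rate,
    current = samples)
  attr(w, "sample_rate") <- spec$sample_rate
  attr(w, "pulses") <- pulses
  attr(w, "spec") <- spec
  class(w) <- c("pac_waveform", class(w))
  w
}

#' Pulse-event annotations of a waveform
#'
#' @param w A `pac_waveform`.
#' @return Tibble with `onset_time`, `instantaneous_frequency`, `amplitude`.
#' @export
pulse_events <- function(w) attr(w, "pulses")

#' @export
print.pac_waveform <- function(x, ...) {
  spec <- attr(x, "spec")
  cat(sprintf("<pac_waveform> %s: %d samples @ %g Hz (%g s), %d pulses\n",
              spec$waveform_kind, nrow(x), spec$sample_rate, spec$duration,
              nrow(pulse_events(x))))
  NextMethod()
}

#' Generate a dithered phase-amplitude-coupled pulse train
#'
#' The core brain-mimetic stimulus: biphasic square pulses fired at a
#' Gaussian-dithered rate centred on `f_h`, each pulse's amplitude set by
#' the instantaneous phase of a `f_l` Hz sinusoid,
#' `a(t) = a0 * sin(2 pi f_l t)` (or its rectified variant).
#'
#' @param spec A [stim_spec()] with `waveform_kind = "depacer"`.
#' @return A `pac_waveform`: a tibble (`time`, `current`) carrying the
#'   sample rate, the pulse-event table and the generating spec as
#'   attributes.
#' @examples
#' w <- generate_depacer(stim_spec(duration = 2))
#' range(w$current)
#' @export
generate_depacer <- function(spec) {
  validate_stim_spec(spec)
  if (spec$waveform_kind != "depacer")
    stop("spec$waveform_kind must be 'depacer'", call. = FALSE)
  pulses <- sample_pulse_times(spec)
  pulses$amplitude <- envelope_at(2 * pi * spec$f_l * pulses$onset_time,
                                  spec$a0, spec$envelope_mode)
  samples <- place_pulses(pulses, spec, function(a)
    render_biphasic_pulse(a, spec$pulse_width, spec$sample_rate))
  new_waveform(samples, pulses, spec)
}

#' Generate a mono-rhythmic control pulse train
#'
#' Constant-amplitude biphasic pulses at exactly `f_l` (`"lfs"`) or `f_h`
#' (`"hfs"`), no dither, no envelope modulation. The first pulse fires at
#' t = 0, so a train of duration `d` holds `floor(d * f)` pulses.
#'
#' @param spec A [stim_spec()] with `waveform_kind` `"lfs"` or `"hfs"`.
#' @return A `pac_waveform`.
#' @export
generate_monorhythmic <- function(spec) {
  validate_stim_spec(spec)
  if (!spec$waveform_kind %in% c("lfs", "hfs"))
    stop("spec$waveform_kind must be 'lfs' or 'hfs'", call. = FALSE)
  f <- if (spec$waveform_kind == "lfs") spec$f_l else spec$f_h
  n_pulses <- floor(spec$duration * f)
  pulses <- tibble::tibble(
    onset_time = (seq_len(n_pulses) - 1) / f,
    instantaneous_frequency = rep(f, n_pulses),
    amplitude = rep(spec$a0, n_pulses))
  samples <- place_pulses(pulses, spec, function(a)
    render_biphasic_pulse(a, spec$pulse_width, spec$sample_rate))
  new_waveform(samples, pulses, spec)
}

#' Generate a kindling train
#'
#' Monophasic square pulses of 0.5 ms at 60 Hz for 2 s — the
#' afterdischarge-evoking stimulus used to kindle and later to evoke
#' seizures. Currents outside the conventional 10–150 uA range warn but do
#' not error, so dose-series sweeps can run freely.
#'
#' @param current Pulse current, uA.
#' @param sample_rate Hz; default 10000.
#' @param rate Pulse rate, Hz; default 60.
#' @param duration Train duration, s; default 2.
#' @param pulse_width Monophasic pulse duration, ms; default 0.5.
#' @return A `pac_waveform` (monophasic: all samples >= 0 for positive
#'   current).
#' @export
generate_kindling_train <- function(current, sample_rate = 10000,
                                    rate = 60, duration = 2,
                                    pulse_width = 0.5) {
  if (current < 10 || current > 150)
    warning("kindling current ", current,
            " uA is outside the conventional 10-150 uA range")
  spec <- stim_spec(f_l = 1, f_h = rate, dither_spread = 0, a0 = current,
                    pulse_width = pulse_width, sample_rate = sample_rate,
                    duration = duration, waveform_kind = "kindling")
  n_pulses <- floor(duration * rate)
  pulses <- tibble::tibble(
    onset_time = (seq_len(n_pulses) - 1) / rate,
    instantaneous_frequency = rep(rate, n_pulses),
    amplitude = rep(current, n_pulses))
  pw <- as.integer(round(pulse_width * sample_rate / 1000))
  samples <- place_pulses(pulses, spec, function(a) rep(a, pw))
  new_waveform(samples, pulses, spec)
}

#' Export a waveform to a stimulator-ready text file
#'
#' Plain text, UTF-8, LF line endings: `#`-prefixed header lines recording
#' the sample rate, every spec field and the seed, then one current value
#' per line. Round-trips bit-exactly through [read_waveform()].
#'
#' @param w A `pac_waveform`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
export_waveform <- function(w, path) {
  spec <- attr(w, "spec")
  header <- c(
    "# pacstim waveform v1",
    sprintf("# waveform_kind: %s", spec$waveform_kind),
    sprintf("# sample_rate: %s", format_num(spec$sample_rate)),
    sprintf("# f_l: %s", format_num(spec$f_l)),
    sprintf("# f_h: %s", format_num(spec$f_h)),
    sprintf("# dither_spread: %s", format_num(spec$dither_spread)),
    sprintf("# a0: %s", format_num(spec$a0)),
    sprintf("# pulse_width: %s", format_num(spec$pulse_width)),
    sprintf("# duration: %s", format_num(spec$duration)),
    sprintf("# seed: %d", spec$seed),
    sprintf("# envelope_mode: %s", spec$envelope_mode))
  con <- file(path, open = "wb")  # wb => LF endings on every platform
  on.exit(close(con))
  writeLines(c(header, format_num(w$current)), con, sep = "\n")
  invisible(path)
}

# shortest decimal representation that survives as.numeric() exactly
format_num <- function(x) {
  out <- formatC(x, format = "g", digits = 15)
  bad <- as.numeric(out) != x
  if (any(bad)) out[bad] <- formatC(x[bad], format = "g", digits = 17)
  trimws(out)
}

#' Read a waveform text file written by [export_waveform()]
#'
#' @param path File path.
#' @return A `pac_waveform`. Pulse-event annotations are not stored in the
#'   text format; the returned waveform carries an empty pulse table (the
#'   embedded seed and spec allow regeneration).
#' @export
read_waveform <- function(path) {
  lines <- readLines(path)
  is_header <- startsWith(lines, "#")
  hdr <- lines[is_header]
  body <- lines[!is_header]
  get_field <- function(key) {
    m <- grep(paste0("^# ", key, ": "), hdr, value = TRUE)
    if (length(m) != 1) stop("malformed waveform header: missing ", key,
                             call. = FALSE)
    sub(paste0("^# ", key, ": "), "", m)
  }
  spec <- stim_spec(
    f_l = as.numeric(get_field("f_l")),
    f_h = as.numeric(get_field("f_h")),
    dither_spread = as.numeric(get_field("dither_spread")),
    a0 = as.numeric(get_field("a0")),
    pulse_width = as.numeric(get_field("pulse_width")),
    sample_rate = as.numeric(get_field("sample_rate")),
    duration = as.numeric(get_field("duration")),
    seed = as.integer(get_field("seed")),
    envelope_mode = get_field("envelope_mode"),
    waveform_kind = get_field("waveform_kind"))
  samples <- as.numeric(body)
  if (anyNA(samples)) stop("malformed waveform body", call. = FALSE)
  new_waveform(samples, tibble::tibble(onset_time = numeric(),
                                       instantaneous_frequency = numeric(),
                                       amplitude = numeric()), spec)
}
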