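#' Stimulus specification
#'
#' Bundles every parameter needed to synthesize a stimulation waveform:
#' the low-frequency rhythm rate `f_l` whose phase modulates pulse
#' amplitude, the mean high-frequency pulse rate `f_h`, the Gaussian
#' spread of the per-pulse instantaneous frequency (`dither_spread`, a
#' standard deviation in Hz), the peak envelope amplitude `a0`, the
#' biphasic pulse width, sample rate, duration and RNG seed.
#'
#' `dither_spread` is interpreted as the standard deviation of the
#' per-pulse instantaneous-frequency distribution. The raw parameter is
#' exposed directly, so a variance reading (e.g. 10 Hz^2, i.e. an SD of
#' `sqrt(10)` Hz) can be configured by passing `sqrt(v)` instead.
#'
#' @param f_l Low-frequency (envelope) rhythm rate, Hz. Default 1.
#' @param f_h Mean high-frequency pulse rate, Hz. Default 100.
#' @param dither_spread Standard deviation of the per-pulse instantaneous
#'   frequency, Hz. 0 gives an exactly periodic train. Default 10.
#' @param a0 Peak envelope amplitude, uA. Default 40.
#' @param pulse_width Total duration of one biphasic pulse, ms. Must span a
#'   whole (and, for biphasic pulses, even) number of samples. Default 1.
#' @param sample_rate Samples per second, Hz. Default 10000.
#' @param duration Waveform length, s. Default 30.
#' @param seed Integer RNG seed for the dither draws.
#' @param envelope_mode One of `"signed_sine"` (pulse amplitude
#'   `a0*sin(phase)`, polarity flips on the negative half-cycle),
#'   `"rectified_sine"` (`a0*(1+sin(phase))/2`, always non-negative) or
#'   `"constant"` (every pulse at `a0`; the degenerate no-modulation case).
#' @param waveform_kind One of `"depacer"`, `"lfs"`, `"hfs"`, `"kindling"`.
#'
#' @return An object of class `stim_spec` (a validated named list).
#' @examples
#' stim_spec(duration = 2)
#' @export
stim_spec <- function(f_l = 1, f_h = 100, dither_spread = 10, a0 = 40,
                      pulse_width = 1, sample_rate = 10000, duration = 30,
                      seed = 1L,
                      envelope_mode = c("signed_sine", "rectified_sine",
                                        "constant"),
                      waveform_kind = c("depacer", "lfs", "hfs",
                                        "kindling")) {
  envelope_mode <- match.arg(envelope_mode)
  waveform_kind <- match.arg(waveform_kind)
  spec <- structure(
    list(f_l = f_l, f_h = f_h, dither_spread = dither_spread, a0 = a0,
         pulse_width = pulse_width, sample_rate = sample_rate,
         duration = duration, seed = as.integer(seed),
         envelope_mode = envelope_mode, waveform_kind = waveform_kind),
    class = "stim_spec")
  validate_stim_spec(spec)
}

validate_stim_spec <- function(spec) {
  stopifnot(inherits(spec, "stim_spec"))
  with(spec, {
    if (f_l <= 0) stop("f_l must be > 0", call. = FALSE)
    if (f_h <= 0) stop("f_h must be > 0", call. = FALSE)
    if (dither_spread < 0) stop("dither_spread must be >= 0", call. = FALSE)
    if (a0 < 0) stop("a0 must be >= 0", call. = FALSE)
    if (duration <= 0) stop("duration must be > 0", call. = FALSE)
    if (sample_rate <= 0) stop("sample_rate must be > 0", call. = FALSE)
    pw_samples <- pulse_width * sample_rate / 1000
    if (abs(pw_samples - round(pw_samples)) > 1e-9 || round(pw_samples) < 1)
      stop("pulse_width must span a positive whole number of samples at ",
           "sample_rate (got ", pw_samples, " samples)", call. = FALSE)
    # pulses must not overlap at the mean rate
    if (f_h * pulse_width / 1000 >= 1)
      stop("f_h * pulse_width must be < 1 s/s: pulses would overlap at the ",
           "mean rate", call. = FALSE)
  })
  spec
}

pulse_width_samples <- function(spec) {
  as.integer(round(spec$pulse_width * spec$sample_rate / 1000))
}

#' @export
print.stim_spec <- function(x, ...) {
  cat("<stim_spec> ", x$waveform_kind, "\n", sep = "")
  cat(sprintf("  f_l %g Hz | f_h %g Hz | dither SD %g Hz | a0 %g uA\n",
              x$f_l, x$f_h, x$dither_spread, x$a0))
  cat(sprintf("  pulse width %g ms | %g Hz sampling | %g s | seed %d | %s\n",
              x$pulse_width, x$sample_rate, x$duration, x$seed,
              x$envelope_mode))
  invisible(x)
}
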