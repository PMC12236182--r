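#' Complex Morlet wavelet parameters
#'
#' The mother wavelet is
#' `Psi(t) = (1 / sqrt(pi * fb)) * exp(2i pi fc t) * exp(-t^2 / fb)`,
#' with central frequency `fc` and bandwidth parameter `fb`. An analysis
#' frequency `f` is reached at scale `a = fc / f`; the scaled wavelet is
#' L1-normalized (`psi_a(t) = Psi(t / a) / a`) and doubled (analytic-signal
#' convention), so a pure tone of amplitude `A` at a grid frequency has
#' `|W| ~= A` there, independent of frequency — which is what makes
#' amplitudes comparable across frequencies in coupling analyses.
#'
#' Defaults `fc = 0.8125`, `fb = 5` are the values conventionally used for
#' EEG work with this wavelet family.
#'
#' @param fc Central frequency, Hz.
#' @param fb Bandwidth parameter (Gaussian width of the envelope, as it
#'   appears in the formula above).
#' @param frequency_grid Strictly increasing analysis frequencies, Hz.
#'   Default: logarithmic, 8 voices per octave from 0.5 to 512 Hz.
#' @return A `wavelet_params` object.
#' @export
wavelet_params <- function(fc = 0.8125, fb = 5,
                           frequency_grid = log_freq_grid(0.5, 512, 8)) {
  if (fc <= 0 || fb <= 0) stop("fc and fb must be > 0", call. = FALSE)
  if (length(frequency_grid) < 1 || any(diff(frequency_grid) <= 0))
    stop("frequency_grid must be non-empty and strictly increasing",
         call. = FALSE)
  structure(list(fc = fc, fb = fb, frequency_grid = frequency_grid),
            class = "wavelet_params")
}

#' Logarithmic frequency grid
#'
#' @param from,to Range endpoints, Hz (both included when `to/from` is a
#'   power of two at the chosen density).
#' @param voices_per_octave Grid points per frequency doubling.
#' @return Numeric vector of frequencies.
#' @export
log_freq_grid <- function(from, to, voices_per_octave = 4) {
  n_oct <- log2(to / from)
  2^seq(log2(from), log2(to), by = 1 / voices_per_octave)
}

#' Continuous wavelet transform with a complex Morlet wavelet
#'
#' FFT-based convolution of the signal with the scaled mother wavelet at
#' every grid frequency, using reflection padding at the edges. Samples
#' inside the cone of influence — within 3 Gaussian standard deviations
#' (`3 * a * sqrt(fb / 2)` seconds) of either edge — are flagged in the
#' `coi` matrix; they are contaminated by the boundary.
#'
#' @param x Numeric signal (finite) or a single-channel recording tibble
#'   with a `current`/channel column; plain numeric is expected here.
#' @param sample_rate Hz.
#' @param params A [wavelet_params()]; frequencies must lie below the
#'   Nyquist frequency.
#' @return A `pac_scalogram`: list with complex `coefficients`
#'   (time x frequency), `times`, `freqs`, logical `coi` (TRUE = inside
#'   the cone of influence), `params`, `sample_rate`.
#' @examples
#' fs <- 256
#' x <- sin(2 * pi * 8 * seq(0, 2, by = 1 / fs))
#' s <- morlet_cwt(x, fs, wavelet_params(frequency_grid = c(4, 8, 16)))
#' @export
morlet_cwt <- function(x, sample_rate, params = wavelet_params()) {
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x)))
    stop("signal must be finite numeric", call. = FALSE)
  freqs <- params$frequency_grid
  if (length(freqs) == 0) stop("empty frequency grid", call. = FALSE)
  if (any(freqs >= sample_rate / 2))
    stop("analysis frequencies must be below the Nyquist frequency (",
         sample_rate / 2, " Hz)", call. = FALSE)
  n <- length(x)
  W <- matrix(0 + 0i, nrow = n, ncol = length(freqs))
  coi <- matrix(FALSE, nrow = n, ncol = length(freqs))
  fs <- sample_rate
  for (j in seq_along(freqs)) {
    a <- params$fc / freqs[j]
    sigma_t <- a * sqrt(params$fb / 2)            # Gaussian SD, s
    half <- min(n, max(2L, ceiling(4 * sigma_t * fs)))
    tk <- (-half:half) / fs
    # conjugate-correlation kernel, L1 scale normalization, x2 analytic
    psi <- (2 / (a * sqrt(pi * params$fb))) *
      exp(-2i * pi * params$fc * tk / a) * exp(-(tk / a)^2 / params$fb)
    xp <- c(rev(x[seq_len(half)]), x, rev(x[n - seq_len(half) + 1L]))
    W[, j] <- fft_convolve_valid(xp, psi) / fs
    edge <- min(n, ceiling(3 * sigma_t * fs))
    coi[c(seq_len(edge), n - seq_len(edge) + 1L), j] <- TRUE
  }
  structure(list(coefficients = W,
                 times = (seq_len(n) - 1L) / fs,
                 freqs = freqs, coi = coi, params = params,
                 sample_rate = fs),
            class = "pac_scalogram")
}

# 'valid' part of conv(x, rev(Conj(k))) -- correlation of x with kernel k
# centred per sample; length(x) = n + 2*half, kernel length 2*half + 1.
fft_convolve_valid <- function(x, k) {
  n_out <- length(x) - length(k) + 1L
  nf <- stats::nextn(length(x), 2)
  X <- stats::fft(c(x, rep(0, nf - length(x))))
  K <- stats::fft(c(Conj(k), rep(0, nf - length(k))))
  full <- stats::fft(X * K, inverse = TRUE) / nf
  full[seq(length(k), length.out = n_out)]
}

#' @export
print.pac_scalogram <- function(x, ...) {
  cat(sprintf("<pac_scalogram> %d samples x %d frequencies (%g-%g Hz) @ %g Hz\n",
              nrow(x$coefficients), length(x$freqs), min(x$freqs),
              max(x$freqs), x$sample_rate))
  invisible(x)
}

#' @importFrom tibble as_tibble
#' @method as_tibble pac_scalogram
#' @export
as_tibble.pac_scalogram <- function(x, ...) {
  tidyr::expand_grid(time = x$times, freq = x$freqs) |>
    dplyr::mutate(
      magnitude = as.vector(t(Mod(x$coefficients))),
      phase = as.vector(t(Arg(x$coefficients))),
      in_coi = as.vector(t(x$coi)))
}

#' Baseline statistics of a scalogram
#'
#' Per-frequency mean and standard deviation of the coefficient magnitude
#' `|W|` over a declared baseline interval, using only samples the epoch
#' mask marks valid.
#'
#' @param s A `pac_scalogram`.
#' @param baseline `c(start, end)` in seconds, half-open `[start, end)`.
#' @param mask Optional logical vector (length = number of samples); FALSE
#'   samples (stimulation epochs and guard margins) are excluded.
#' @param power If TRUE use `|W|^2` (spectral power) instead of amplitude.
#' @return Tibble: `freq`, `mean`, `sd`, `n`.
#' @export
baseline_stats <- function(s, baseline, mask = NULL, power = FALSE) {
  keep <- s$times >= baseline[1] & s$times < baseline[2]
  if (!is.null(mask)) {
    stopifnot(length(mask) == length(s$times))
    keep <- keep & mask
  }
  if (!any(keep))
    stop("baseline interval contains no unmasked samples", call. = FALSE)
  M <- Mod(s$coefficients[keep, , drop = FALSE])
  if (power) M <- M^2
  tibble::tibble(
    freq = s$freqs,
    mean = colMeans(M),
    sd = apply(M, 2, stats::sd),
    n = sum(keep))
}

#' z-score a scalogram against a pre-stimulation baseline
#'
#' `z(t, f) = (|W(t, f)| - mu_f) / sigma_f`, with `mu_f`, `sigma_f`
#' estimated from the unmasked samples of the baseline interval. Masked
#' samples propagate as `NA` in the z-map rather than being zero-filled.
#'
#' @inheritParams baseline_stats
#' @return A `pac_zmap`: list with real matrix `z` (time x frequency,
#'   `NA` where masked), `times`, `freqs`, `mask`, `baseline`,
#'   `sample_rate`.
#' @export
zscore_scalogram <- function(s, baseline, mask = NULL, power = FALSE) {
  bs <- baseline_stats(s, baseline, mask, power = power)
  bad <- !is.finite(bs$sd) | bs$sd <= 0
  if (any(bad))
    stop("zero baseline standard deviation at frequency ",
         paste(signif(bs$freq[bad], 4), collapse = ", "),
         " Hz", call. = FALSE)
  M <- Mod(s$coefficients)
  if (power) M <- M^2
  z <- sweep(sweep(M, 2, bs$mean), 2, bs$sd, "/")
  if (!is.null(mask)) z[!mask, ] <- NA_real_
  structure(list(z = z, times = s$times, freqs = s$freqs,
                 mask = mask %||% rep(TRUE, length(s$times)),
                 baseline = baseline, sample_rate = s$sample_rate),
            class = "pac_zmap")
}

#' @export
print.pac_zmap <- function(x, ...) {
  cat(sprintf("<pac_zmap> %d samples x %d frequencies, baseline [%g, %g) s\n",
              nrow(x$z), length(x$freqs), x$baseline[1], x$baseline[2]))
  invisible(x)
}

#' Band-averaged summary of a z-map or scalogram
#'
#' Mean over unmasked (non-`NA`) time points within `interval` and over
#' grid frequencies inside `band`.
#'
#' @param x A `pac_zmap` or `pac_scalogram`.
#' @param band `c(f_lo, f_hi)` Hz, inclusive; must contain at least one
#'   grid frequency.
#' @param interval `c(start, end)` seconds, half-open; default the full
#'   extent.
#' @return A single number.
#' @export
band_power <- function(x, band, interval = NULL) {
  vals <- if (inherits(x, "pac_zmap")) x$z else Mod(x$coefficients)
  times <- x$times
  in_band <- x$freqs >= band[1] & x$freqs <= band[2]
  if (!any(in_band))
    stop("band [", band[1], ", ", band[2], "] Hz contains no grid frequency",
         call. = FALSE)
  keep <- if (is.null(interval)) rep(TRUE, length(times)) else
    times >= interval[1] & times < interval[2]
  sel <- vals[keep, in_band, drop = FALSE]
  if (all(is.na(sel)) || length(sel) == 0)
    stop("empty selection: no unmasked samples in interval", call. = FALSE)
  mean(sel, na.rm = TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
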