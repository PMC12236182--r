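#' Extract the phase time-series at one frequency
#'
#' The phase is the two-argument arctangent of the complex wavelet
#' coefficient at frequency `f` (the printed shorthand `arctan(Im/Re)`
#' resolved to `atan2` so quadrants are unambiguous), wrapped to
#' `(-pi, pi]`.
#'
#' Two conventions are offered. `"sine"` (default) reports the phase `phi`
#' such that the band-limited signal is `A * sin(phi)` — the same
#' convention in which the stimulus envelope is written `a0 * sin(phi)`,
#' so a sinusoid's maxima sit at `phi = pi/2`. `"cosine"` is the raw
#' analytic-signal angle (`A * cos(phi)`, maxima at 0), which satisfies
#' exact antisymmetry under coefficient conjugation. The modulation index
#' is invariant to the choice (a constant phase rotation).
#'
#' @param s A `pac_scalogram`.
#' @param f A frequency present in the scalogram grid.
#' @param convention `"sine"` or `"cosine"`.
#' @return Numeric vector of phases, radians in `(-pi, pi]`.
#' @export
extract_phase <- function(s, f, convention = c("sine", "cosine")) {
  convention <- match.arg(convention)
  j <- match_freq(s, f)
  ph <- Arg(s$coefficients[, j])
  if (convention == "sine") ph <- wrap_phase(ph + pi / 2)
  ph
}

#' Extract the amplitude time-series at one frequency
#'
#' The modulus of the complex wavelet coefficient,
#' `A(t, f) = |Re W + i Im W|`; always non-negative.
#'
#' @inheritParams extract_phase
#' @return Non-negative numeric vector.
#' @export
extract_amplitude <- function(s, f) {
  j <- match_freq(s, f)
  Mod(s$coefficients[, j])
}

match_freq <- function(s, f) {
  j <- which(abs(s$freqs - f) <= 1e-9 * pmax(1, abs(f)))
  if (length(j) != 1)
    stop("frequency ", f, " Hz is not in the scalogram grid", call. = FALSE)
  j
}

# wrap to (-pi, pi]
wrap_phase <- function(x) {
  out <- (x + pi) %% (2 * pi) - pi
  out[out == -pi] <- pi
  out
}

#' Phase-amplitude coupling strength (modulation index)
#'
#' Tort-style coupling strength: phases are binned into `n_bins` equal
#' bins (default 18, i.e. 20 degree bins), the mean amplitude per bin is
#' normalized to a distribution `P`, and the index is the
#' Kullback-Leibler distance of `P` from the uniform distribution,
#' normalized by its maximum:
#' `MI = (log(n_bins) - H(P)) / log(n_bins)`, in `[0, 1]`.
#' 0 means the fast rhythm's amplitude is flat over slow-rhythm phase; 1
#' means all amplitude mass concentrates in a single phase bin. Empty
#' phase bins contribute zero mean amplitude (`0 * log 0 = 0` in the
#' entropy).
#'
#' @param phase Phases, radians (any wrapping).
#' @param amp Amplitudes, non-negative, same length as `phase`. Pairs with
#'   `NA` in either series are dropped (masked samples).
#' @param n_bins Number of phase bins (>= 4).
#' @return MI scalar in `[0, 1]`.
#' @examples
#' ph <- seq(-pi, pi, length.out = 1000)
#' modulation_index(ph, 1 + 0.8 * sin(ph))
#' @export
modulation_index <- function(phase, amp, n_bins = 18) {
  stopifnot(length(phase) == length(amp), n_bins >= 4)
  keep <- !is.na(phase) & !is.na(amp)
  phase <- phase[keep]; amp <- amp[keep]
  if (length(phase) < n_bins)
    stop("need at least n_bins unmasked samples", call. = FALSE)
  if (all(amp == 0)) stop("all-zero amplitude series", call. = FALSE)
  bin <- phase_bin(phase, n_bins)
  sums <- vapply(split(amp, factor(bin, levels = seq_len(n_bins))),
                 sum, numeric(1))
  cnts <- tabulate(bin, nbins = n_bins)
  means <- ifelse(cnts > 0, sums / pmax(cnts, 1L), 0)
  mi_from_bin_means(means)
}

phase_bin <- function(phase, n_bins) {
  # equal bins partitioning (-pi, pi]; bin k covers (-pi + (k-1)w, -pi + kw]
  w <- 2 * pi / n_bins
  b <- ceiling((wrap_phase(phase) + pi) / w)
  b[b < 1L] <- 1L
  b[b > n_bins] <- n_bins
  b
}

mi_from_bin_means <- function(means) {
  p <- means / sum(means)
  h <- -sum(ifelse(p > 0, p * log(p), 0))
  (log(length(p)) - h) / log(length(p))
}

#' Comodulogram parameters
#'
#' @param phase_freqs Phase (slow) frequency grid, Hz. Default 1-32 Hz,
#'   logarithmic, 4 voices per octave (21 points).
#' @param amp_freqs Amplitude (fast) frequency grid, Hz. Default
#'   32-512 Hz, logarithmic, 4 voices per octave (17 points).
#' @param n_phase_bins Phase bins; default 18 (20 degree bins).
#' @param window Sliding-window length, s; default 4 (allows at least 4
#'   cycles at a 1 Hz phase floor). Must be >= `4 / min(phase_freqs)`.
#' @param stride Window advance, s; default 1.
#' @return A `comodulogram_params` object.
#' @export
comodulogram_params <- function(phase_freqs = log_freq_grid(1, 32, 4),
                                amp_freqs = log_freq_grid(32, 512, 4),
                                n_phase_bins = 18, window = 4,
                                stride = 1) {
  if (n_phase_bins < 4) stop("n_phase_bins must be >= 4", call. = FALSE)
  if (window < 4 / min(phase_freqs))
    stop("window must cover at least 4 cycles of the slowest phase ",
         "frequency (>= ", 4 / min(phase_freqs), " s)", call. = FALSE)
  structure(list(phase_freqs = phase_freqs, amp_freqs = amp_freqs,
                 n_phase_bins = n_phase_bins, window = window,
                 stride = stride),
            class = "comodulogram_params")
}

#' Sliding-window phase-amplitude comodulogram
#'
#' For every window and every (phase frequency, amplitude frequency) pair,
#' the modulation index of the amplitude series over the binned phase
#' series, both taken from the same Morlet scalogram. Windows advance by
#' `stride`; a window whose samples are all masked is omitted from the
#' output (not NA-filled).
#'
#' @param s A `pac_scalogram` whose grid contains all requested phase and
#'   amplitude frequencies (build it with
#'   `wavelet_params(frequency_grid = sort(union(phase_freqs, amp_freqs)))`).
#' @param p A [comodulogram_params()].
#' @param mask Optional logical validity vector (FALSE = masked).
#' @return A `pac_comodulogram`: tibble with `window_start` (s),
#'   `f_phase`, `f_amp` (Hz) and `mi`, carrying `p` as an attribute.
#' @export
comodulogram <- function(s, p = comodulogram_params(), mask = NULL) {
  n <- length(s$times)
  fs <- s$sample_rate
  wlen <- round(p$window * fs)
  if (n < wlen) stop("recording shorter than one window", call. = FALSE)
  if (is.null(mask)) mask <- rep(TRUE, n)
  starts_idx <- seq(1L, n - wlen + 1L, by = max(1L, round(p$stride * fs)))

  phase_mat <- vapply(p$phase_freqs, function(f) extract_phase(s, f),
                      numeric(n))
  amp_mat <- vapply(p$amp_freqs, function(f) extract_amplitude(s, f),
                    numeric(n))
  nb <- p$n_phase_bins

  res <- purrr::map(starts_idx, function(s0) {
    idx <- seq(s0, s0 + wlen - 1L)
    idx <- idx[mask[idx]]
    if (length(idx) < nb) return(NULL)
    mi <- matrix(NA_real_, length(p$phase_freqs), length(p$amp_freqs))
    for (i in seq_along(p$phase_freqs)) {
      bin <- phase_bin(phase_mat[idx, i], nb)
      cnts <- tabulate(bin, nbins = nb)
      grouped <- rowsum(amp_mat[idx, , drop = FALSE], bin)
      lev <- as.integer(rownames(grouped))
      for (j in seq_along(p$amp_freqs)) {
        sums <- numeric(nb)
        sums[lev] <- grouped[, j]
        means <- ifelse(cnts > 0, sums / pmax(cnts, 1L), 0)
        mi[i, j] <- if (sum(means) > 0) mi_from_bin_means(means) else 0
      }
    }
    tidyr::expand_grid(f_phase = p$phase_freqs, f_amp = p$amp_freqs) |>
      dplyr::mutate(window_start = s$times[s0],
                    mi = as.vector(t(mi)), .before = 1)
  })
  out <- dplyr::bind_rows(res)
  attr(out, "params") <- p
  class(out) <- c("pac_comodulogram", class(out))
  out
}

#' Mean comodulogram across windows
#'
#' @param cm A `pac_comodulogram`.
#' @return Tibble `f_phase`, `f_amp`, `mi` averaged over windows.
#' @export
pool_comodulogram <- function(cm) {
  dplyr::summarise(dplyr::group_by(tibble::as_tibble(cm), f_phase, f_amp),
                   mi = mean(mi), .groups = "drop")
}

#' Surrogate significance floor for the modulation index
#'
#' Recomputes MI on circularly time-shifted copies of the amplitude
#' series (uniform random shift of at least `min_shift` seconds, which
#' destroys phase-amplitude alignment while preserving both marginals)
#' and returns the 95th percentile — a significance floor for observed
#' MI values.
#'
#' @inheritParams modulation_index
#' @param sample_rate Hz (to express the minimum shift in samples).
#' @param n_surrogates Number of shifted copies; >= 19.
#' @param seed RNG seed.
#' @param min_shift Minimum circular shift, s; default 1.
#' @param probs Quantile to return; default 0.95.
#' @return MI threshold (scalar).
#' @export
surrogate_threshold <- function(phase, amp, sample_rate,
                                n_surrogates = 200, seed = 1,
                                n_bins = 18, min_shift = 1,
                                probs = 0.95) {
  if (n_surrogates < 19) stop("n_surrogates must be >= 19", call. = FALSE)
  n <- length(phase)
  if (n / sample_rate < 2)
    stop("series must be at least 2 s long", call. = FALSE)
  min_s <- round(min_shift * sample_rate)
  old <- saved_rng_state()
  set.seed(seed)
  on.exit(restore_rng(old), add = TRUE)
  shifts <- sample(seq(min_s, n - min_s), n_surrogates, replace = TRUE)
  mis <- vapply(shifts, function(k) {
    modulation_index(phase, c(amp[(k + 1):n], amp[1:k]), n_bins)
  }, numeric(1))
  unname(stats::quantile(mis, probs, type = 7))
}
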