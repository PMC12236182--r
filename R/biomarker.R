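#' A single stimulation probe trial
#'
#' One interictal probe: a recording segment holding a pre-stimulation
#' baseline, a stimulation epoch of a given amplitude (masked during
#' analysis because of the stimulation artifact), and a post-stimulation
#' evaluation interval.
#'
#' @param recording A `pac_recording` (see [read_recording()]) or a
#'   numeric trace.
#' @param epoch `c(start, end)` of the stimulation epoch, s (half-open).
#' @param amplitude Stimulation amplitude, uA.
#' @param pre `c(start, end)` baseline interval preceding the epoch;
#'   default from recording start to epoch start.
#' @param post `c(start, end)` evaluation interval; default 60 s starting
#'   1 s after the epoch ends (guard margin against residual artifact).
#' @param channel Channel to analyse when `recording` is multi-channel.
#' @param sample_rate Required when `recording` is a bare numeric vector.
#' @return A `probe_trial` object.
#' @export
probe_trial <- function(recording, epoch, amplitude, pre = NULL,
                        post = NULL, channel = NULL, sample_rate = NULL) {
  if (is.numeric(recording) && is.null(dim(recording))) {
    if (is.null(sample_rate)) stop("sample_rate required for numeric trace",
                                   call. = FALSE)
    x <- recording
    fs <- sample_rate
  } else {
    fs <- attr(recording, "sample_rate")
    chans <- setdiff(names(recording), "time")
    channel <- channel %||% chans[1]
    x <- recording[[channel]]
  }
  dur <- length(x) / fs
  pre <- pre %||% c(0, epoch[1])
  post <- post %||% c(epoch[2] + 1, min(dur, epoch[2] + 61))
  if (pre[1] >= pre[2] || pre[2] > epoch[1])
    stop("pre-interval must precede the stimulation epoch", call. = FALSE)
  if (post[1] < epoch[2])
    stop("post-interval must follow the stimulation epoch", call. = FALSE)
  structure(list(x = x, sample_rate = fs, epoch = epoch,
                 amplitude = amplitude, pre = pre, post = post),
            class = "probe_trial")
}

#' Frequency band definition
#'
#' @param name Band name.
#' @param f_lo,f_hi Band edges, Hz; `0 < f_lo < f_hi`.
#' @return A `band_definition`. [delta_band()] is the 1-4 Hz default used
#'   by the dose-response biomarker (standard EEG convention; the bounds
#'   are configurable).
#' @export
band_definition <- function(name, f_lo, f_hi) {
  if (!(f_lo > 0 && f_lo < f_hi))
    stop("need 0 < f_lo < f_hi", call. = FALSE)
  structure(list(name = name, f_lo = f_lo, f_hi = f_hi),
            class = "band_definition")
}

#' @rdname band_definition
#' @export
delta_band <- function() band_definition("delta", 1, 4)

#' Post-stimulation band change in baseline z units
#'
#' z-scores the Morlet scalogram of a probe trial against its
#' pre-stimulation interval (stimulation-epoch samples plus a guard
#' margin are masked and excluded from both the baseline statistics and
#' the summary), then returns the mean z over the band in the
#' post-interval. Negative values mean suppression relative to baseline.
#'
#' @param trial A [probe_trial()].
#' @param band A [band_definition()]; default [delta_band()].
#' @param wavelet A [wavelet_params()]; its frequency grid is restricted
#'   to (a neighbourhood of) the band. Default: 8 voices/octave across
#'   the band.
#' @param guard Guard margin around the stimulation epoch, s; default 1.
#' @param min_baseline Minimum unmasked baseline length, s; default 30.
#' @return Signed z summary (scalar).
#' @export
delta_change <- function(trial, band = delta_band(), wavelet = NULL,
                         guard = 1, min_baseline = 30) {
  fs <- trial$sample_rate
  wavelet <- wavelet %||% wavelet_params(
    frequency_grid = log_freq_grid(band$f_lo, band$f_hi, 8))
  n <- length(trial$x)
  times <- (seq_len(n) - 1L) / fs
  mask <- !(times >= trial$epoch[1] - guard & times < trial$epoch[2] + guard)
  base_keep <- mask & times >= trial$pre[1] & times < trial$pre[2]
  if (sum(base_keep) / fs < min_baseline)
    stop("need at least ", min_baseline,
         " s of unmasked baseline", call. = FALSE)
  s <- morlet_cwt(trial$x, fs, wavelet)
  z <- zscore_scalogram(s, trial$pre, mask = mask)
  band_power(z, c(band$f_lo, band$f_hi), trial$post)
}

#' Ascending-amplitude dose-response assessment
#'
#' Runs [delta_change()] over a series of probe trials of strictly
#' increasing stimulation amplitude and reports the detected threshold:
#' the smallest amplitude whose band change falls at or below the
#' suppression criterion (default z <= -1.96), or none if never met.
#' Detection is deterministic given the recordings — no randomness inside.
#'
#' @param trials List of [probe_trial()]s, amplitudes strictly increasing.
#' @param band,wavelet,guard,min_baseline Passed to [delta_change()].
#' @param criterion Suppression criterion in baseline z units;
#'   default -1.96.
#' @return A `dose_response` object: `table` (tibble `amplitude`,
#'   `delta_z`, `suppressed`), `threshold` (uA or `NA`), `criterion`,
#'   `band`. Has [tidy()]/[glance()]/[autoplot()] methods.
#' @export
run_dose_series <- function(trials, band = delta_band(), wavelet = NULL,
                            criterion = -1.96, guard = 1,
                            min_baseline = 30) {
  if (length(trials) < 2) stop("need at least 2 amplitudes", call. = FALSE)
  amps <- vapply(trials, function(t) t$amplitude, numeric(1))
  if (any(diff(amps) <= 0))
    stop("trial amplitudes must be strictly increasing", call. = FALSE)
  z <- vapply(trials, delta_change, numeric(1), band = band,
              wavelet = wavelet, guard = guard,
              min_baseline = min_baseline)
  tab <- tibble::tibble(amplitude = amps, delta_z = z,
                        suppressed = z <= criterion)
  hit <- which(tab$suppressed)
  structure(list(table = tab,
                 threshold = if (length(hit)) amps[min(hit)] else NA_real_,
                 criterion = criterion, band = band),
            class = "dose_response")
}

#' @export
print.dose_response <- function(x, ...) {
  cat(sprintf("<dose_response> %s band [%g, %g] Hz, criterion z <= %g\n",
              x$band$name, x$band$f_lo, x$band$f_hi, x$criterion))
  print(x$table)
  if (is.na(x$threshold)) cat("no threshold detected\n")
  else cat("detected threshold:", x$threshold, "uA\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @method tidy dose_response
#' @export
tidy.dose_response <- function(x, ...) x$table

#' @method glance dose_response
#' @export
glance.dose_response <- function(x, ...) {
  tibble::tibble(threshold = x$threshold, criterion = x$criterion,
                 n_amplitudes = nrow(x$table),
                 min_delta_z = min(x$table$delta_z))
}

#' Paired two-group comparison (Wilcoxon signed-rank)
#'
#' Two-sided Wilcoxon signed-rank test on paired samples, the convention
#' for comparing seizure durations with and without stimulation. The
#' exact null distribution is used for n <= 25 when there are no ties or
#' zero differences; otherwise the normal approximation with tie
#' correction. Per-group mean and standard error of the mean are reported
#' alongside (the field's reporting convention).
#'
#' @param values_a,values_b Paired numeric vectors, equal length n >= 5.
#' @return A `paired_test` object with `statistic` (V), `p_value`,
#'   `method`, and per-group `mean_a`, `sem_a`, `mean_b`, `sem_b`.
#'   Has [tidy()]/[glance()] methods.
#' @export
paired_group_test <- function(values_a, values_b) {
  n <- length(values_a)
  if (n != length(values_b)) stop("groups must be paired (equal length)",
                                  call. = FALSE)
  if (n < 5) stop("need n >= 5 pairs", call. = FALSE)
  d <- values_a - values_b
  if (all(d == 0))
    stop("all paired differences are zero: signed-rank statistic undefined",
         call. = FALSE)
  nz <- d[d != 0]          # zero differences dropped, as is conventional
  exact <- length(nz) <= 25
  if (exact) {
    res <- exact_signrank(nz)
    statistic <- res$statistic
    p_value <- res$p_value
  } else {
    ht <- suppressWarnings(
      stats::wilcox.test(values_a, values_b, paired = TRUE,
                         alternative = "two.sided", exact = FALSE,
                         correct = TRUE))
    statistic <- unname(ht$statistic)
    p_value <- ht$p.value
  }
  sem <- function(v) stats::sd(v) / sqrt(length(v))
  structure(list(statistic = statistic, p_value = p_value,
                 method = if (exact) "exact" else "normal approximation",
                 n = n,
                 mean_a = mean(values_a), sem_a = sem(values_a),
                 mean_b = mean(values_b), sem_b = sem(values_b)),
            class = "paired_test")
}

#' @export
print.paired_test <- function(x, ...) {
  cat(sprintf("Wilcoxon signed-rank (%s), n = %d: V = %g, p = %.4g\n",
              x$method, x$n, x$statistic, x$p_value))
  cat(sprintf("  group A %.3g +/- %.3g (SEM); group B %.3g +/- %.3g\n",
              x$mean_a, x$sem_a, x$mean_b, x$sem_b))
  invisible(x)
}

#' @method tidy paired_test
#' @export
tidy.paired_test <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, p_value = x$p_value,
                 method = x$method, n = x$n)
}

#' @method glance paired_test
#' @export
glance.paired_test <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, p_value = x$p_value,
                 method = x$method, n = x$n,
                 mean_a = x$mean_a, sem_a = x$sem_a,
                 mean_b = x$mean_b, sem_b = x$sem_b)
}

# Exact two-sided signed-rank p-value for the nonzero differences d,
# valid with tied |d| (midranks): the null distribution of V = sum of
# positive-difference ranks is built by dynamic programming over the
# doubled midranks (integers), i.e. the generating polynomial
# prod_i (1 + x^(2 r_i)) of all 2^n equiprobable sign assignments.
# stats::wilcox.test refuses exact p-values under ties; the tie-aware
# exact distribution is computed here for n <= 25.
exact_signrank <- function(d) {
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  r2 <- as.integer(round(2 * r))        # midranks doubled -> integers
  total <- sum(r2)
  counts <- numeric(total + 1)          # counts[s + 1] = #assignments
  counts[1] <- 1
  for (ri in r2) {
    shifted <- c(rep(0, ri), counts[seq_len(total + 1 - ri)])
    counts <- counts + shifted
  }
  probs <- counts / sum(counts)
  v2 <- round(2 * v_obs)
  lower <- sum(probs[seq_len(v2 + 1)])
  upper <- sum(probs[seq(v2 + 1, total + 1)])
  list(statistic = v_obs, p_value = min(1, 2 * min(lower, upper)))
}

#' Duration of the afterdischarge evoked by a stimulus
#'
#' Detects how long supra-threshold epileptiform activity outlasts an
#' evoked stimulus using a line-length feature (sum of absolute
#' first differences) in 1-s windows: windows after the stimulus whose
#' line length exceeds `k` times the baseline mean count as
#' afterdischarge, and the duration runs from the stimulus to the end of
#' the first contiguous supra-threshold run. Returns 0 if no window
#' exceeds threshold within `onset_tolerance` of the stimulus. The
#' feature is baseline-relative, so the result is invariant to overall
#' signal gain. This detector is deliberately simple scaffolding — any
#' monotone afterdischarge detector would do for synthetic validation —
#' and is not a clinical seizure detector.
#'
#' @param recording A `pac_recording` or numeric trace.
#' @param evoked_time Time of the evoked stimulus, s; needs >= 10 s of
#'   recording after it.
#' @param k Threshold multiplier over baseline line length; default 3.
#' @param window Feature window, s; default 1.
#' @param baseline `c(start, end)` interval for the baseline line length;
#'   default everything before `evoked_time`, excluding samples masked by
#'   the recording's stimulation-epoch annotations.
#' @param onset_tolerance Latest post-stimulus start (s) for a run to
#'   count as evoked; default 10 (afterdischarges may follow the evoking
#'   train after several seconds of latency).
#' @param max_gap Number of consecutive sub-threshold windows a run may
#'   bridge (brief mid-discharge attenuations are scored as part of the
#'   event); default 1.
#' @param channel,sample_rate As in [probe_trial()].
#' @return Afterdischarge duration, s.
#' @export
evoked_duration <- function(recording, evoked_time, k = 3, window = 1,
                            baseline = NULL, onset_tolerance = 10,
                            max_gap = 1, channel = NULL,
                            sample_rate = NULL) {
  if (is.numeric(recording) && is.null(dim(recording))) {
    if (is.null(sample_rate)) stop("sample_rate required for numeric trace",
                                   call. = FALSE)
    x <- recording
    fs <- sample_rate
    mask <- rep(TRUE, length(x))
  } else {
    fs <- attr(recording, "sample_rate")
    chans <- setdiff(names(recording), "time")
    channel <- channel %||% chans[1]
    x <- recording[[channel]]
    mask <- epoch_mask(recording)
  }
  n <- length(x)
  dur <- n / fs
  if (evoked_time < 0 || evoked_time > dur)
    stop("evoked_time outside recording", call. = FALSE)
  if (dur - evoked_time < 10)
    stop("need at least 10 s of recording after the evoked stimulus",
         call. = FALSE)
  wlen <- round(window * fs)
  ll <- function(seg) sum(abs(diff(seg)))

  base_int <- baseline %||% c(0, evoked_time)
  times <- (seq_len(n) - 1L) / fs
  base_starts <- seq(base_int[1], base_int[2] - window, by = window)
  base_ll <- vapply(base_starts, function(t0) {
    idx <- which(times >= t0 & times < t0 + window & mask)
    if (length(idx) < wlen) NA_real_ else ll(x[idx])
  }, numeric(1))
  base_ll <- base_ll[!is.na(base_ll)]
  if (length(base_ll) == 0)
    stop("no unmasked baseline windows before the evoked stimulus",
         call. = FALSE)
  thr <- k * mean(base_ll)

  post_starts <- seq(evoked_time, dur - window, by = window)
  supra <- vapply(post_starts, function(t0) {
    i0 <- floor(t0 * fs) + 1L
    idx <- i0:min(n, i0 + wlen - 1L)
    if (!all(mask[idx])) return(NA)  # stimulation-gated window: unscorable
    ll(x[idx]) > thr
  }, logical(1))
  valid <- which(!is.na(supra))
  if (!length(valid)) return(0)
  # onset tolerance counts from the first scorable post-stimulus window
  t_ref <- post_starts[valid[1]]
  hits <- valid[supra[valid]]
  if (!length(hits) || post_starts[hits[1]] - t_ref > onset_tolerance)
    return(0)
  first <- hits[1]
  run_end <- first
  gap <- 0L
  i <- first
  while (i < length(supra)) {
    i <- i + 1L
    if (isTRUE(supra[i])) {
      run_end <- i
      gap <- 0L
    } else {
      gap <- gap + 1L
      if (gap > max_gap) break
    }
  }
  (post_starts[run_end] + window) - evoked_time
}
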