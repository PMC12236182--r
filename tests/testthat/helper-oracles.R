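# Independent oracles used across tests. These deliberately re-derive
# quantities by the most literal route available (explicit loops,
# enumeration, numerical integration) so they share no code with the
# implementation they check.

# Tort-style MI by explicit histogram loop over explicit bin edges
mi_oracle <- function(phase, amp, n_bins = 18) {
  edges <- seq(-pi, pi, length.out = n_bins + 1)
  ph <- (phase + pi) %% (2 * pi) - pi
  ph[ph == -pi] <- pi
  means <- numeric(n_bins)
  for (j in seq_len(n_bins)) {
    in_bin <- ph > edges[j] & ph <= edges[j + 1]
    means[j] <- if (any(in_bin)) mean(amp[in_bin]) else 0
  }
  p <- means / sum(means)
  h <- 0
  for (pj in p) if (pj > 0) h <- h - pj * log(pj)
  (log(n_bins) - h) / log(n_bins)
}

# exact two-sided signed-rank p-value by enumerating all 2^n sign vectors
wilcoxon_exact_oracle <- function(a, b) {
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- as.vector(signs %*% r)
  mu <- n * (n + 1) / 4
  # two-sided: double the smaller tail (matches the exact distribution
  # convention when no ties are present)
  p <- 2 * min(mean(v_all >= v_obs), mean(v_all <= v_obs))
  min(1, p)
}

# mean and SD of Normal(mu, sigma^2) truncated to [lo, Inf) by
# numerical integration
truncnorm_moments <- function(mu, sigma, lo) {
  z <- stats::pnorm(lo, mu, sigma, lower.tail = FALSE)
  m1 <- stats::integrate(function(x) x * stats::dnorm(x, mu, sigma),
                         lo, Inf)$value / z
  m2 <- stats::integrate(function(x) x^2 * stats::dnorm(x, mu, sigma),
                         lo, Inf)$value / z
  c(mean = m1, sd = sqrt(m2 - m1^2))
}

# log-log periodogram slope over a frequency range
periodogram_slope <- function(x, fs, f_lo, f_hi) {
  n <- length(x)
  spec <- Mod(stats::fft(x))[2:(n %/% 2)]^2
  freq <- (1:(n %/% 2 - 1)) * fs / n
  keep <- freq >= f_lo & freq <= f_hi
  unname(stats::coef(stats::lm(log(spec[keep]) ~ log(freq[keep])))[2])
}
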