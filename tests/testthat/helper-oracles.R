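# Independent oracles used across test files. These deliberately avoid the
# package's own code paths.

# Plain one-sided periodogram (rectangular window, full series, FFT direct),
# scaled as a density so that sum(psd) * df ~ var(x).
periodogram_oracle <- function(x, fs) {
  n <- length(x)
  xc <- x - mean(x)
  P <- Mod(stats::fft(xc))^2 / (fs * n)
  n_half <- floor(n / 2) + 1
  psd <- P[seq_len(n_half)]
  psd[2:(n_half - 1)] <- 2 * psd[2:(n_half - 1)]
  if (n %% 2 == 1) psd[n_half] <- 2 * psd[n_half]
  list(frequency = (seq_len(n_half) - 1) * fs / n, psd = psd,
       resolution = fs / n)
}

# Rectangle-rule band integral of an oracle periodogram over [lo, hi).
band_integral_oracle <- function(spec, lo, hi) {
  sel <- spec$frequency >= lo & spec$frequency < hi
  sum(spec$psd[sel]) * spec$resolution
}

# Benjamini-Hochberg adjusted p-values by the direct definition
# adj_(i) = min_{j >= i} m * p_(j) / j (computed on sorted values).
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  sorted <- p[o]
  adj_sorted <- numeric(m)
  for (i in seq_len(m)) {
    adj_sorted[i] <- min(1, min(m * sorted[i:m] / (i:m)))
  }
  adj <- numeric(m)
  adj[o] <- adj_sorted
  adj
}

# Residualize-then-correlate partial correlation oracle via lm().
partial_corr_oracle <- function(x, y, z) {
  rx <- stats::residuals(stats::lm(x ~ z))
  ry <- stats::residuals(stats::lm(y ~ z))
  r <- stats::cor(rx, ry)
  df <- length(x) - 3
  tt <- r * sqrt(df / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(tt), df))
}

# An IBI series whose beats tile [0, dur] at a constant period (ms).
constant_ibi <- function(period_ms = 800, dur = 900) {
  tb <- seq(period_ms / 1000, dur, by = period_ms / 1000)
  s <- data.frame(beat_time_s = tb, ibi_ms = period_ms)
  class(s) <- c("ibi_series", "data.frame")
  s
}

# Beats at fixed spacing carrying a sinusoidally modulated IBI value.
sinusoid_ibi <- function(pace_s, dur = 270, base = 850, amp = 80,
                         spacing = 0.85) {
  tb <- seq(spacing, dur, by = spacing)
  s <- data.frame(beat_time_s = tb,
                  ibi_ms = base + amp * sin(2 * pi * tb / pace_s))
  class(s) <- c("ibi_series", "data.frame")
  s
}
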