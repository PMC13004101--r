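#' Standard and custom HRV frequency bands
#'
#' Band edges in Hz. Alongside the standard low-frequency (LF, 0.04-0.15 Hz)
#' and high-frequency (HF, 0.15-0.4 Hz) bands, three custom sub-bands
#' subdivide the baroreflex range: lower LF (0.058-0.068 Hz), middle LF
#' (0.075-0.093 Hz) and upper LF (0.096-0.130 Hz); the baroreflex band itself
#' spans 0.075-0.130 Hz. Band intervals are half-open `[lo, hi)` so adjacent
#' bands never double-count a frequency bin.
#'
#' @param total_range Range used for "total power", Hz (default 0.04-0.40).
#' @return Named list of `c(lo, hi)` pairs.
#' @export
hrv_bands <- function(total_range = c(0.04, 0.40)) {
  list(
    total_power = total_range,
    lf          = c(0.040, 0.150),
    hf          = c(0.150, 0.400),
    lower_lf    = c(0.058, 0.068),
    middle_lf   = c(0.075, 0.093),
    upper_lf    = c(0.096, 0.130),
    baroreflex  = c(0.075, 0.130)
  )
}

#' Segment a session into trimmed 5-minute regimes
#'
#' Splits a 15-minute session into three regimes, trims `trim` seconds at
#' each regime boundary (to absorb pace transitions), and flags each regime
#' as included when it holds at least `min_usable` seconds of usable data.
#' Usable duration is the length of the trimmed window actually covered by
#' beats, computed as the union of the per-beat intervals
#' `[beat_time - ibi, beat_time]` intersected with the window; a fully
#' covered regime yields exactly `regime_length - 2 * trim` seconds
#' (4 min 30 s under the defaults).
#'
#' @param series An `ibi_series` data frame (`beat_time_s`, `ibi_ms`).
#' @param regime_length Regime length, s (default 300).
#' @param trim Seconds trimmed at each end of every regime (default 15).
#' @param min_usable Minimum usable seconds for inclusion (default 210,
#'   i.e. 3 min 30 s).
#' @param n_regimes Number of regimes per session (default 3).
#'
#' @return A list of `regime_segment` objects, each a list with
#'   `regime_index`, `beats` (the retained `ibi_series` rows),
#'   `usable_duration` (s), `included` (logical) and `window` (c(start, end)).
#' @examples
#' set.seed(3)
#' ibi <- simulate_ibi(breathing_schedule("slow", paces = c(10, 12, 15)),
#'                     sim_config())
#' sapply(segment_session(ibi), `[[`, "usable_duration")
#' @export
segment_session <- function(series, regime_length = 300, trim = 15,
                            min_usable = 210, n_regimes = 3) {
  if (nrow(series) > 0 && is.unsorted(series$beat_time_s, strictly = TRUE)) {
    stop("beat times must be strictly increasing")
  }
  if (nrow(series) == 0 ||
      max(series$beat_time_s) < regime_length) {
    warning("session shorter than one regime; all segments excluded")
  }
  lapply(seq_len(n_regimes), function(i) {
    w0 <- (i - 1) * regime_length + trim
    w1 <- i * regime_length - trim
    keep <- series$beat_time_s >= w0 & series$beat_time_s < w1
    beats <- series[keep, , drop = FALSE]
    usable <- coverage_length(series$beat_time_s, series$ibi_ms, w0, w1)
    structure(
      list(regime_index = i, beats = beats, usable_duration = usable,
           included = usable >= min_usable, window = c(w0, w1)),
      class = "regime_segment"
    )
  })
}

# Length of the union of beat coverage intervals [t - ibi, t] within [w0, w1].
coverage_length <- function(beat_time, ibi_ms, w0, w1) {
  if (length(beat_time) == 0) return(0)
  lo <- pmax(beat_time - ibi_ms / 1000, w0)
  hi <- pmin(beat_time, w1)
  ok <- hi > lo
  if (!any(ok)) return(0)
  lo <- lo[ok]; hi <- hi[ok]
  # beat times are sorted, so intervals are sorted by start; merge in one pass
  total <- 0
  cur_lo <- lo[1]; cur_hi <- hi[1]
  for (j in seq_along(lo)[-1]) {
    if (lo[j] <= cur_hi) {
      cur_hi <- max(cur_hi, hi[j])
    } else {
      total <- total + (cur_hi - cur_lo)
      cur_lo <- lo[j]; cur_hi <- hi[j]
    }
  }
  total + (cur_hi - cur_lo)
}

#' Remove ectopic beats and artifacts from an IBI series
#'
#' A beat is rejected when its IBI deviates from the running median
#' (window of `window` beats) by more than `rel_threshold` as a fraction of
#' that median. This stands in for the proprietary correction applied by
#' commercial pulse-sensor software; the threshold is configurable.
#'
#' @param series An `ibi_series` data frame.
#' @param rel_threshold Maximum tolerated fractional deviation (default 0.25).
#' @param window Running-median window in beats (odd; default 11).
#'
#' @return The cleaned `ibi_series`. Attributes `n_removed` and
#'   `removed_fraction` record the cleaning extent; when more than 20% of
#'   beats are removed the result carries `flagged_unusable = TRUE` and a
#'   warning is issued.
#' @export
clean_ibi <- function(series, rel_threshold = 0.25, window = 11) {
  n <- nrow(series)
  if (n == 0) return(series)
  k <- min(window, if (n %% 2 == 1) n else n - 1)
  if (k < 3) {
    med <- rep(stats::median(series$ibi_ms), n)
  } else {
    med <- stats::runmed(series$ibi_ms, k = k, endrule = "median")
  }
  keep <- abs(series$ibi_ms - med) <= rel_threshold * med
  out <- series[keep, , drop = FALSE]
  class(out) <- c("ibi_series", "data.frame")
  attr(out, "n_removed") <- sum(!keep)
  attr(out, "removed_fraction") <- mean(!keep)
  if (mean(!keep) > 0.20) {
    attr(out, "flagged_unusable") <- TRUE
    warning(sprintf("%.0f%% of beats removed (> 20%%); segment flagged unusable",
                    100 * mean(!keep)))
  } else {
    attr(out, "flagged_unusable") <- FALSE
  }
  out
}

#' Interpolate an IBI segment to an evenly sampled heart-period series
#'
#' Cubic-spline interpolation of (beat time, IBI) onto a uniform 4-Hz grid
#' spanning the segment's beats; with fewer than 4 beats a linear
#' interpolation is used instead. No extrapolation beyond the first and last
#' beat.
#'
#' @param segment A `regime_segment` (from [segment_session()]) or an
#'   `ibi_series` data frame.
#' @param rate Sampling rate of the output grid, Hz (default 4).
#'
#' @return An object of class `hr_series`: list with `time` (s), `ibi_ms`
#'   (interpolated heart period) and `rate`.
#' @export
interpolate_hr <- function(segment, rate = 4) {
  beats <- if (inherits(segment, "regime_segment")) segment$beats else segment
  n <- nrow(beats)
  if (n < 2) stop("need at least 2 beats to interpolate, got ", n)
  t0 <- beats$beat_time_s[1]
  t1 <- beats$beat_time_s[n]
  grid <- seq(t0, t1, by = 1 / rate)
  vals <- if (n >= 4) {
    stats::spline(beats$beat_time_s, beats$ibi_ms, xout = grid,
                  method = "fmm")$y
  } else {
    stats::approx(beats$beat_time_s, beats$ibi_ms, xout = grid)$y
  }
  structure(list(time = grid, ibi_ms = vals, rate = rate),
            class = "hr_series")
}

#' Time-domain HRV metrics over 60-second windows
#'
#' RMSSD (root mean square of successive IBI differences) and SDNN (sample
#' standard deviation of IBIs) are computed within consecutive 60-s windows
#' of the segment and averaged across windows. Windows holding fewer than 3
#' beats are skipped.
#'
#' @param segment A `regime_segment` or an `ibi_series` data frame.
#' @param window_s Window length in seconds (default 60).
#' @return Named numeric vector `c(rmssd =, sdnn =)` in ms; `NA` when no
#'   window has enough beats.
#' @export
time_domain <- function(segment, window_s = 60) {
  beats <- if (inherits(segment, "regime_segment")) segment$beats else segment
  if (nrow(beats) < 3) return(c(rmssd = NA_real_, sdnn = NA_real_))
  t0 <- beats$beat_time_s[1]
  win <- floor((beats$beat_time_s - t0) / window_s)
  per_win <- lapply(split(beats$ibi_ms, win), function(x) {
    if (length(x) < 3) return(NULL)
    c(rmssd = sqrt(mean(diff(x)^2)), sdnn = stats::sd(x))
  })
  per_win <- per_win[!vapply(per_win, is.null, logical(1))]
  if (length(per_win) == 0) return(c(rmssd = NA_real_, sdnn = NA_real_))
  m <- do.call(rbind, per_win)
  c(rmssd = mean(m[, "rmssd"]), sdnn = mean(m[, "sdnn"]))
}

#' Welch power spectral density of a uniformly sampled series
#'
#' Welch's method: the series is split into segments (default 270 s, one
#' full trimmed regime) with 50% overlap, each segment is linearly detrended,
#' tapered with a Hann window, and its one-sided periodogram computed;
#' periodograms are averaged across segments. Density scaling is such that
#' the integral of the PSD over all frequencies approximates the series
#' variance. The default segment length gives a 1/270 Hz grid, fine enough
#' to resolve the narrow custom LF sub-bands (the narrowest spans only
#' 0.01 Hz); for a single trimmed regime this reduces to one Hann-tapered
#' periodogram.
#'
#' @param x Numeric series or an `hr_series`.
#' @param fs Sampling rate, Hz (taken from an `hr_series` input).
#' @param seg_seconds Welch segment length, s (default 270). When the series
#'   is shorter than one segment the whole series is used as a single
#'   segment.
#' @param overlap Fractional segment overlap (default 0.5).
#' @param detrend Linearly detrend each segment before tapering
#'   (default TRUE).
#'
#' @return Object of class `spectral_estimate`: list with `frequency` (Hz,
#'   uniform grid from 0 to Nyquist), `psd` (ms^2/Hz), and `resolution`
#'   (grid spacing, Hz).
#' @export
welch_psd <- function(x, fs = 4, seg_seconds = 270, overlap = 0.5,
                      detrend = TRUE) {
  if (inherits(x, "hr_series")) {
    fs <- x$rate
    x <- x$ibi_ms
  }
  n <- length(x)
  if (n < 8) stop("series too short for spectral estimation (n = ", n, ")")
  L <- min(n, round(seg_seconds * fs))
  step <- max(1L, floor(L * (1 - overlap)))
  starts <- seq(1L, n - L + 1L, by = step)
  w <- 0.5 * (1 - cos(2 * pi * seq_len(L) / L))  # periodic Hann
  scale <- 2 / (fs * sum(w^2))
  n_half <- floor(L / 2) + 1L
  acc <- numeric(n_half)
  for (s in starts) {
    seg <- x[s:(s + L - 1L)]
    if (detrend) {
      idx <- seq_len(L)
      fit <- stats::lm.fit(cbind(1, idx), seg)
      seg <- fit$residuals
    } else {
      seg <- seg - mean(seg)
    }
    X <- stats::fft(seg * w)[seq_len(n_half)]
    p <- scale * (Mod(X)^2)
    p[1] <- p[1] / 2                        # DC not doubled
    if (L %% 2 == 0) p[n_half] <- p[n_half] / 2  # Nyquist not doubled
    acc <- acc + p
  }
  psd <- acc / length(starts)
  structure(
    list(frequency = (seq_len(n_half) - 1) * fs / L, psd = psd,
         resolution = fs / L),
    class = "spectral_estimate"
  )
}

#' Integrate a PSD over a half-open frequency band
#'
#' Band power is the rectangle-rule integral of the PSD over bins with
#' frequency in `[lo, hi)`.
#'
#' @param spec A `spectral_estimate`.
#' @param lo,hi Band edges, Hz.
#' @param band Band name used in error messages.
#' @return Band power (ms^2).
#' @export
band_power <- function(spec, lo, hi, band = deparse(substitute(lo))) {
  fmax <- max(spec$frequency) + spec$resolution
  if (lo < 0 || hi > fmax) {
    stop(sprintf("band '%s' [%g, %g) Hz lies outside the spectral grid [0, %g) Hz",
                 band, lo, hi, fmax))
  }
  sel <- spec$frequency >= lo & spec$frequency < hi
  sum(spec$psd[sel]) * spec$resolution
}

#' Spectral band powers of an interpolated heart-period series
#'
#' @param hr An `hr_series` (uniformly sampled, typically 4 Hz). A warning is
#'   issued when the series spans less than 210 s.
#' @param bands Named list of `c(lo, hi)` band edges (default [hrv_bands()]).
#' @param ... Passed to [welch_psd()].
#' @return List with `spectrum` (the `spectral_estimate`) and `powers`
#'   (named vector of band powers, ms^2).
#' @export
spectral_power <- function(hr, bands = hrv_bands(), ...) {
  stopifnot(inherits(hr, "hr_series"))
  dur <- diff(range(hr$time))
  if (dur < 210) {
    warning(sprintf("series spans %.0f s (< 210 s); spectral estimate unstable",
                    dur))
  }
  spec <- welch_psd(hr, ...)
  powers <- vapply(names(bands), function(b) {
    band_power(spec, bands[[b]][1], bands[[b]][2], band = b)
  }, numeric(1))
  list(spectrum = spec, powers = powers)
}

#' Full HRV metric record for one regime
#'
#' Convenience wrapper: time-domain metrics, mean heart rate and spectral
#' band powers for one included regime.
#'
#' @param segment An included `regime_segment`.
#' @param bands Band list (default [hrv_bands()]).
#' @param rate Interpolation rate, Hz.
#' @param ... Passed to [welch_psd()].
#' @return One-row data frame with columns `rmssd`, `sdnn`, `mean_hr` (bpm)
#'   and one column per band.
#' @export
regime_metrics <- function(segment, bands = hrv_bands(), rate = 4, ...) {
  stopifnot(inherits(segment, "regime_segment"))
  if (!segment$included) stop("regime ", segment$regime_index, " not included")
  td <- time_domain(segment)
  hr <- interpolate_hr(segment, rate = rate)
  sp <- spectral_power(hr, bands = bands, ...)
  out <- data.frame(rmssd = td[["rmssd"]], sdnn = td[["sdnn"]],
                    mean_hr = 60000 / mean(hr$ibi_ms))
  for (b in names(sp$powers)) out[[b]] <- sp$powers[[b]]
  out
}

#' Per-regime HRV metrics for a whole session
#'
#' Cleans the IBI series, segments it into trimmed regimes, and computes
#' [regime_metrics()] for every included regime.
#'
#' @param series Raw `ibi_series` for one session.
#' @param bands Band list.
#' @param clean Apply [clean_ibi()] first (default TRUE).
#' @param ... Passed to [segment_session()].
#' @return Data frame with one row per included regime (zero rows when none
#'   qualify), plus a `regime_index` column.
#' @export
session_metrics <- function(series, bands = hrv_bands(), clean = TRUE, ...) {
  if (clean) series <- clean_ibi(series)
  segs <- segment_session(series, ...)
  rows <- lapply(segs, function(s) {
    if (!s$included) return(NULL)
    cbind(regime_index = s$regime_index, regime_metrics(s, bands = bands))
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) {
    return(data.frame())
  }
  do.call(rbind, rows)
}

#' Aggregate regime-level HRV records into one subject-level record
#'
#' Arithmetic mean of each metric over all included regimes of all sessions,
#' with natural-log variants of every power metric and of RMSSD/SDNN. By
#' default the log is applied to the averaged raw metric (log-of-mean);
#' mean-of-logs is available via `log_of_mean = FALSE`.
#'
#' @param records Data frame of regime-level metrics (rows from
#'   [session_metrics()] over all of a subject's sessions).
#' @param log_of_mean Apply the log after averaging (default TRUE).
#' @return One-row data frame with the averaged metrics plus `log_<metric>`
#'   columns, or a one-row all-`NA` frame (with a message) when no regime is
#'   available.
#' @export
aggregate_subject <- function(records, log_of_mean = TRUE) {
  metric_cols <- setdiff(names(records), "regime_index")
  loggable <- setdiff(metric_cols, "mean_hr")
  if (is.null(records) || nrow(records) == 0) {
    message("no included regimes; subject marked missing")
    out <- as.data.frame(as.list(stats::setNames(
      rep(NA_real_, length(metric_cols)), metric_cols)))
    for (m in loggable) out[[paste0("log_", m)]] <- NA_real_
    return(out)
  }
  means <- colMeans(records[, metric_cols, drop = FALSE])
  out <- as.data.frame(as.list(means))
  for (m in loggable) {
    out[[paste0("log_", m)]] <- if (log_of_mean) {
      log(means[[m]])
    } else {
      mean(log(records[[m]]))
    }
  }
  out
}
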