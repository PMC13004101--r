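test_that("regime segmentation trims 15 s at each end and measures coverage", {
  s <- constant_ibi(800, dur = 900)
  segs <- segment_session(s)
  expect_length(segs, 3)
  for (seg in segs) {
    expect_equal(seg$usable_duration, 270)
    expect_true(seg$included)
    expect_true(all(seg$beats$beat_time_s >= seg$window[1]))
    expect_true(all(seg$beats$beat_time_s < seg$window[2]))
  }
})

test_that("regimes with too little usable data are excluded", {
  # beats cover only 200 s of the first trimmed window
  s <- constant_ibi(800, dur = 900)
  short <- s[s$beat_time_s < 215 | s$beat_time_s >= 300, ]
  class(short) <- c("ibi_series", "data.frame")
  segs <- segment_session(short)
  # beats run up to t = 214.4 s, so the trimmed window [15, 285) is covered
  # over [15, 214.4] only
  expect_equal(segs[[1]]$usable_duration, 199.4)
  expect_false(segs[[1]]$included)
  expect_true(segs[[2]]$included)
})

test_that("an empty series yields three excluded segments and a warning", {
  empty <- data.frame(beat_time_s = numeric(0), ibi_ms = numeric(0))
  expect_warning(segs <- segment_session(empty), "shorter than one regime")
  expect_length(segs, 3)
  expect_false(any(vapply(segs, `[[`, logical(1), "included")))
})

test_that("trimming is idempotent: re-segmenting a trimmed regime keeps its beats", {
  s <- constant_ibi(800, dur = 900)
  seg1 <- segment_session(s)[[1]]
  again <- suppressWarnings(
    segment_session(seg1$beats, regime_length = 300, trim = 15))[[1]]
  # the first window [15, 285) already excludes trimmed beats; nothing new goes
  expect_equal(again$beats$beat_time_s, seg1$beats$beat_time_s)
})

test_that("artifact rejection removes planted ectopic beats and only those", {
  s <- constant_ibi(800, dur = 600)
  expect_equal(clean_ibi(s)$ibi_ms, s$ibi_ms)  # artifact-free: identity
  # one beat at 2x the local median
  spike <- s
  spike$ibi_ms[200] <- 1600
  cleaned <- suppressWarnings(clean_ibi(spike))
  expect_equal(attr(cleaned, "n_removed"), 1)
  expect_false(200 %in% match(cleaned$beat_time_s, spike$beat_time_s))
  # brute-force scan oracle: exactly the beats deviating > 25% from the
  # 11-beat running median
  med <- stats::runmed(spike$ibi_ms, 11, endrule = "median")
  oracle_keep <- abs(spike$ibi_ms - med) <= 0.25 * med
  expect_equal(cleaned$ibi_ms, spike$ibi_ms[oracle_keep])
  # 3000-ms spike among 800-ms beats
  spike2 <- s
  spike2$ibi_ms[100] <- 3000
  expect_equal(attr(clean_ibi(spike2), "n_removed"), 1)
})

test_that("heavily corrupted segments are flagged unusable", {
  s <- constant_ibi(800, dur = 300)
  bad <- s
  idx <- seq(1, nrow(s), by = 4)  # 25% of beats corrupted
  bad$ibi_ms[idx] <- 1600
  expect_warning(out <- clean_ibi(bad), "unusable")
  expect_true(attr(out, "flagged_unusable"))
})

test_that("interpolation reproduces constant, linear, and sinusoidal IBI profiles", {
  # constant
  hr <- interpolate_hr(constant_ibi(800, dur = 300))
  expect_true(all(abs(hr$ibi_ms - 800) < 1e-9))
  expect_equal(diff(hr$time)[1], 0.25)
  # two beats: linear midpoint
  two <- data.frame(beat_time_s = c(0, 1), ibi_ms = c(800, 900))
  class(two) <- c("ibi_series", "data.frame")
  hr2 <- interpolate_hr(two)
  expect_equal(hr2$ibi_ms[hr2$time == 0.5], 850)
  expect_error(interpolate_hr(two[1, ]), "at least 2 beats")
  # sinusoid: closed-form oracle, relative RMS error < 5% for pace >= 4 s
  for (pace in c(4, 10)) {
    s <- sinusoid_ibi(pace)
    hr3 <- interpolate_hr(s)
    truth <- 850 + 80 * sin(2 * pi * hr3$time / pace)
    rms <- sqrt(mean((hr3$ibi_ms - truth)^2)) / (80 / sqrt(2))
    expect_lt(rms, 0.05)
  }
  # grid length matches the spanned duration at 4 Hz within one sample
  seg <- segment_session(constant_ibi(800, dur = 900))[[1]]
  hr4 <- interpolate_hr(seg)
  expect_lte(abs(length(hr4$time) - (floor(seg$usable_duration * 4) + 1)), 4)
})

test_that("time-domain metrics follow their defining formulas per 60-s window", {
  # alternating 800/810 ms: rmssd = 10 in every window
  tb <- cumsum(rep(c(0.800, 0.810), 180))
  s <- data.frame(beat_time_s = tb,
                  ibi_ms = rep(c(800, 810), 180))
  class(s) <- c("ibi_series", "data.frame")
  td <- time_domain(s)
  expect_equal(unname(td["rmssd"]), 10, tolerance = 1e-9)
  # each window holds ~equal counts of 800 and 810, so SDNN -> 5 ms
  expect_equal(unname(td["sdnn"]), 5, tolerance = 0.05)
  # a segment shorter than one window equals the whole-segment computation
  short <- s[s$beat_time_s <= 50, ]
  class(short) <- c("ibi_series", "data.frame")
  td2 <- time_domain(short)
  expect_equal(unname(td2["rmssd"]), sqrt(mean(diff(short$ibi_ms)^2)))
  expect_equal(unname(td2["sdnn"]), sd(short$ibi_ms))
})

test_that("Welch band powers agree with a brute-force periodogram oracle", {
  fs <- 4; dur <- 270
  t <- seq(0, dur - 1 / fs, by = 1 / fs)
  n <- length(t)
  # exact-bin sinusoids across the LF range
  for (k in c(12, 23, 27)) {           # 0.0444, 0.0852, 0.1 Hz
    f0 <- k * fs / n
    x <- 850 + 60 * sin(2 * pi * f0 * t)
    sp <- welch_psd(x, fs = fs)
    orc <- periodogram_oracle(x, fs)
    p_impl <- band_power(sp, 0.04, 0.15)
    p_orc <- band_integral_oracle(orc, 0.04, 0.15)
    expect_lt(abs(p_impl - p_orc) / p_orc, 0.01)
    expect_equal(p_impl, 60^2 / 2, tolerance = 0.01 * 60^2 / 2)
  }
})

test_that("white-noise total power satisfies Parseval on average", {
  set.seed(11)
  sigma <- 30
  totals <- replicate(500, {
    x <- rnorm(1080, sd = sigma)
    sp <- welch_psd(x, fs = 4)
    sum(sp$psd) * sp$resolution
  })
  expect_lt(abs(mean(totals) - sigma^2) / sigma^2, 0.15)
})

test_that("sinusoids concentrate LF power in the sub-band containing them", {
  fs <- 4; dur <- 270
  t <- seq(0, dur - 1 / fs, by = 1 / fs)
  probes <- list(upper_lf = 0.1, middle_lf = 1 / 12, lower_lf = 17 / 270)
  bands <- hrv_bands()
  for (b in names(probes)) {
    x <- 850 + 60 * sin(2 * pi * probes[[b]] * t)
    sp <- welch_psd(x, fs = fs)
    frac <- band_power(sp, bands[[b]][1], bands[[b]][2]) /
      band_power(sp, 0.04, 0.15)
    expect_gt(frac, 0.9)
  }
})

test_that("band edges echo the configured values and bad bands error", {
  bands <- hrv_bands()
  expect_equal(bands$upper_lf, c(0.096, 0.130))
  expect_equal(bands$middle_lf, c(0.075, 0.093))
  expect_equal(bands$lower_lf, c(0.058, 0.068))
  expect_equal(bands$baroreflex, c(0.075, 0.130))
  expect_equal(bands$lf, c(0.04, 0.15))
  expect_equal(bands$hf, c(0.15, 0.40))
  sp <- welch_psd(rnorm(1080), fs = 4)
  expect_error(band_power(sp, 1.9, 2.5, band = "beyond"), "beyond")
})

test_that("band powers are additive over partitions and scale quadratically", {
  set.seed(5)
  x <- 850 + as.numeric(arima.sim(list(ar = 0.8), 1080, sd = 10))
  sp <- welch_psd(x, fs = 4)
  # partition [0.04, 0.40) into disjoint half-open bands
  cuts <- c(0.04, 0.09, 0.15, 0.22, 0.40)
  parts <- sum(vapply(seq_len(length(cuts) - 1), function(i) {
    band_power(sp, cuts[i], cuts[i + 1])
  }, numeric(1)))
  expect_equal(parts, band_power(sp, 0.04, 0.40), tolerance = 1e-12)
  # scale equivariance: scaling deviations by c multiplies every power by c^2
  y <- mean(x) + 3 * (x - mean(x))
  spy <- welch_psd(y, fs = 4)
  expect_equal(band_power(spy, 0.04, 0.15), 9 * band_power(sp, 0.04, 0.15),
               tolerance = 1e-9)
})

test_that("subject aggregation averages raw metrics then applies the natural log", {
  recs <- data.frame(regime_index = c(1, 2), rmssd = c(20, 30),
                     sdnn = c(40, 50), mean_hr = c(70, 72),
                     upper_lf = c(100, 300))
  agg <- aggregate_subject(recs)
  expect_equal(agg$upper_lf, 200)
  expect_equal(agg$log_upper_lf, log(200))     # natural log of the mean
  expect_equal(agg$rmssd, 25)
  expect_false("log_mean_hr" %in% names(agg))  # HR is not log-transformed
  # mean-of-logs variant by flag
  agg2 <- aggregate_subject(recs, log_of_mean = FALSE)
  expect_equal(agg2$log_upper_lf, mean(log(c(100, 300))))
  # single record: identity
  agg3 <- aggregate_subject(recs[1, ])
  expect_equal(agg3$upper_lf, 100)
  # zero included regimes: subject marked missing
  expect_message(agg4 <- aggregate_subject(recs[0, ]), "missing")
  expect_true(all(is.na(agg4)))
})

test_that("session_metrics produces one row per included regime", {
  set.seed(9)
  cfg <- sim_config(ibi_noise_sd = 10)
  ibi <- simulate_ibi(breathing_schedule("slow", paces = c(10, 12, 15)), cfg)
  m <- session_metrics(ibi)
  expect_equal(nrow(m), 3)
  expect_true(all(c("rmssd", "sdnn", "mean_hr", "upper_lf", "total_power")
                  %in% names(m)))
  expect_true(all(m$upper_lf >= 0))
  expect_true(all(m$lf + m$hf <= m$total_power + 1e-9))
  expect_true(all(m$middle_lf + m$upper_lf <= m$baroreflex + 1e-9))
  expect_true(all(m$baroreflex <= m$lf + 1e-9))
})
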