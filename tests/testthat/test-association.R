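test_that("partial correlation matches the residualize-then-correlate oracle", {
  set.seed(41)
  # parameterized over several 5-point sets
  for (i in 1:10) {
    z <- rnorm(5); x <- 0.5 * z + rnorm(5); y <- -0.3 * z + rnorm(5)
    pc <- partial_corr(x, y, z)
    orc <- partial_corr_oracle(x, y, z)
    expect_equal(pc$estimate, orc$r, tolerance = 1e-12)
    expect_equal(pc$p.value, orc$p, tolerance = 1e-12)
    expect_equal(pc$df, 2L)
  }
})

test_that("partial correlation is symmetric in x and y and handles nulls", {
  set.seed(42)
  z <- rnorm(60); x <- z + rnorm(60); y <- 2 * z + rnorm(60)
  expect_equal(partial_corr(x, y, z)$estimate, partial_corr(y, x, z)$estimate)
  # x independent of (y, z), n = 500: near-nominal rejection and small |r|
  rejections <- replicate(100, {
    n <- 500
    z <- rnorm(n); y <- z + rnorm(n); x <- rnorm(n)
    pc <- partial_corr(x, y, z)
    c(abs(pc$estimate), pc$p.value < 0.05)
  })
  expect_lt(mean(rejections[1, ]), 0.1)
  expect_lt(abs(mean(rejections[2, ]) - 0.05),
            2 * sqrt(0.05 * 0.95 / 100) + 0.01)
  expect_error(partial_corr(1:3, 1:3, 1:3), "n >= 4")
})

test_that("degenerate covariate relationships are flagged, not computed", {
  z <- rnorm(20); x <- rnorm(20)
  out <- partial_corr(x, z, z)     # y = z exactly: zero-variance residuals
  expect_equal(out$status, "degenerate")
  expect_true(is.na(out$estimate))
})

test_that("spearman variant equals Pearson on ranked-then-residualized data", {
  set.seed(43)
  z <- rnorm(25); x <- exp(z + rnorm(25)); y <- z^3 + rnorm(25)
  pc <- partial_corr(x, y, z, method = "spearman")
  orc <- partial_corr_oracle(rank(x), rank(y), rank(z))
  expect_equal(pc$estimate, orc$r, tolerance = 1e-12)
})

test_that("Shepherd's pi flags planted bivariate outliers and reduces to rho", {
  set.seed(44)
  n <- 50
  z <- rnorm(n); x <- z + rnorm(n); y <- 0.8 * z + x * 0.5 + rnorm(n)
  x[n] <- x[n] + 12; y[n] <- y[n] - 12   # extreme point in residual space
  out <- shepherds_pi(x, y, z)
  expect_true(n %in% out$outliers)
  # pi equals Spearman on the retained residual pairs exactly
  rx <- residuals(lm(x ~ z)); ry <- residuals(lm(y ~ z))
  keep <- setdiff(seq_len(n), out$outliers)
  expect_equal(out$estimate, cor(rx[keep], ry[keep], method = "spearman"),
               tolerance = 1e-12)
  # flags invariant to swapping the residual axes (L1 symmetry)
  out_swap <- shepherds_pi(y, x, z)
  expect_identical(out$outliers, out_swap$outliers)
})

test_that("Shepherd's pi equals rho when no point exceeds the threshold", {
  # symmetric 4-point configuration: all L1 distances tie, so the empirical
  # 99th-percentile equals the maximum and nothing is flagged
  x <- c(1, -1, 2, -2, 1, -1, 2, -2)
  y <- c(2, -2, 1, -1, -2, 2, -1, 1)
  z <- rep(c(0, 1), 4)
  out <- shepherds_pi(x, y, z)
  expect_length(out$outliers, 0)
  rx <- residuals(lm(x ~ z)); ry <- residuals(lm(y ~ z))
  expect_equal(out$estimate, cor(rx, ry, method = "spearman"))
  # doubled-p convention available by flag
  out2 <- shepherds_pi(x, y, z, double_p = TRUE)
  expect_equal(out2$p.value, min(1, 2 * out$p.value))
})

test_that("BH adjustment matches the brute-force step-up oracle", {
  # hand-checked example
  p <- c(0.001, 0.01, 0.02, 0.04, 0.05)
  got <- bh_fdr(p)
  expect_equal(got$adjusted, c(0.005, 0.025, 1 / 30, 0.05, 0.05),
               tolerance = 1e-12)
  expect_true(all(got$significant))
  # single p-value is unchanged
  expect_equal(bh_fdr(0.03)$adjusted, 0.03)
  # all ones: nothing significant
  expect_false(any(bh_fdr(rep(1, 6))$significant))
  # empty input
  expect_length(bh_fdr(numeric(0))$adjusted, 0)
  # random families up to m = 8 against the oracle
  set.seed(45)
  for (m in 2:8) {
    for (i in 1:20) {
      p <- runif(m)^2
      expect_equal(bh_fdr(p)$adjusted, bh_oracle(p), tolerance = 1e-12)
    }
  }
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("the 3xIQR prescreen reports but does not remove", {
  x <- c(rnorm(50), 100)
  flags <- iqr_screen(x)
  expect_true(flags[51])
  expect_equal(sum(flags), 1)
  expect_length(flags, 51)  # nothing dropped
})

test_that("nearest-bin extraction uses minimum distance with low-side ties", {
  spec <- structure(list(frequency = (0:100) / 270, psd = as.numeric(0:100),
                         resolution = 1 / 270),
                    class = "spectral_estimate")
  # target exactly on a grid point: that bin
  expect_equal(nearest_bin_power(spec, 10 / 270), 10)
  # index arithmetic: 0.1 Hz on a 1/270 grid is bin 27
  expect_equal(nearest_bin_power(spec, 0.1), 27)
  # midway between bins: lower bin chosen
  expect_equal(nearest_bin_power(spec, 10.5 / 270), 10)
  expect_error(nearest_bin_power(spec, 0.9), "outside")
})

test_that("the frequency curve spans 0.25 down to 0.05 Hz and localizes effects", {
  set.seed(46)
  n <- 40
  # per-subject synthetic spectra with a subject-varying peak at 0.1 Hz
  strength <- exp(rnorm(n, 0, 0.5))
  f <- (0:135) / 270
  spectra <- lapply(seq_len(n), function(i) {
    psd <- rep(10, length(f)) * exp(rnorm(length(f), 0, 0.1))
    psd[abs(f - 0.1) < 0.006] <- psd[abs(f - 0.1) < 0.006] + 400 * strength[i]
    structure(list(frequency = f, psd = psd, resolution = 1 / 270),
              class = "spectral_estimate")
  })
  pre <- rnorm(n, 7000, 300)
  post <- pre + 100 * scale(log(strength))[, 1] + rnorm(n, 0, 30)
  curve <- frequency_curve(spectra, pre, post)
  expect_equal(nrow(curve), 17)
  expect_equal(curve$frequency_hz[1], 0.25)
  expect_equal(curve$frequency_hz[17], 0.05)
  expect_equal(curve$period_s, 4:20)
  # the planted 0.1-Hz effect peaks at the grid point nearest 0.1 Hz
  expect_equal(curve$period_s[which.max(curve$r)], 10)
  expect_true(curve$fdr_significant[curve$period_s == 10])
})

test_that("a null frequency curve yields few FDR discoveries", {
  set.seed(47)
  n <- 40
  f <- (0:135) / 270
  counts <- replicate(30, {
    spectra <- lapply(seq_len(n), function(i) {
      structure(list(frequency = f,
                     psd = rep(10, length(f)) * exp(rnorm(length(f), 0, 0.3)),
                     resolution = 1 / 270),
                class = "spectral_estimate")
    })
    pre <- rnorm(n, 7000, 300)
    post <- pre + rnorm(n, 0, 50)
    sum(frequency_curve(spectra, pre, post)$fdr_significant)
  })
  expect_lt(mean(counts), 1)
})

test_that("association_table grids metrics by ROI with one FDR family", {
  set.seed(48)
  n <- 30
  metrics <- data.frame(log_upper_lf = rnorm(n), log_hf = rnorm(n))
  changes <- rbind(
    data.frame(subject_id = sprintf("s%02d", 1:n), roi_id = "l_mofc",
               pre = rnorm(n, 7000, 300), post = NA),
    data.frame(subject_id = sprintf("s%02d", 1:n), roi_id = "l_lofc",
               pre = rnorm(n, 9000, 300), post = NA)
  )
  changes$post <- changes$pre +
    ifelse(changes$roi_id == "l_mofc",
           60 * rep(metrics$log_upper_lf, 2)[1:n], 0) + rnorm(2 * n, 0, 40)
  tab <- association_table(metrics, changes,
                           metric_cols = c("log_upper_lf", "log_hf"))
  expect_equal(nrow(tab), 4)
  r_planted <- tab$r[tab$roi_id == "l_mofc" & tab$metric == "log_upper_lf"]
  expect_gt(r_planted, 0.5)
  expect_equal(tab$p_adj, bh_oracle(tab$p), tolerance = 1e-12)
})
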