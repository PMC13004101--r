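#' Residualized partial correlation
#'
#' Correlation between `x` and `y` after each is residualized on the single
#' covariate `z` by least squares (here: post-intervention volume against an
#' HRV metric, controlling pre-intervention volume). For
#' `method = "spearman"` all three variables are rank-transformed first, so
#' the result is a Pearson correlation of ranked-then-residualized variables.
#' The two-tailed p-value uses the t-distribution with n - 3 degrees of
#' freedom.
#'
#' @param x,y Numeric vectors (predictor and outcome; the result is symmetric
#'   in `x` and `y`).
#' @param z Covariate vector.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return Object of class `partial_corr`: list with `estimate`, `p.value`,
#'   `statistic` (t), `df`, `n_used`, `method`, `status` (`"ok"` or
#'   `"degenerate"` when either residual vector has zero variance, in which
#'   case the estimate is `NA`).
#' @examples
#' set.seed(1)
#' z <- rnorm(30); x <- z + rnorm(30); y <- z + rnorm(30)
#' partial_corr(x, y, z)
#' @export
partial_corr <- function(x, y, z, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  ok <- is.finite(x) & is.finite(y) & is.finite(z)
  x <- x[ok]; y <- y[ok]; z <- z[ok]
  n <- length(x)
  if (n < 4) stop("partial correlation needs n >= 4, got ", n)
  if (method == "spearman") {
    x <- rank(x); y <- rank(y); z <- rank(z)
  }
  rx <- stats::lm.fit(cbind(1, z), x)$residuals
  ry <- stats::lm.fit(cbind(1, z), y)$residuals
  out <- list(estimate = NA_real_, p.value = NA_real_,
              statistic = NA_real_, df = n - 3L, n_used = n,
              method = method, status = "ok")
  if (stats::sd(rx) <= 1e-10 * max(stats::sd(x), 1) ||
      stats::sd(ry) <= 1e-10 * max(stats::sd(y), 1)) {
    out$status <- "degenerate"
    class(out) <- "partial_corr"
    return(out)
  }
  r <- stats::cor(rx, ry)
  df <- n - 3
  tstat <- r * sqrt(df / max(1 - r^2, .Machine$double.eps))
  out$estimate <- r
  out$statistic <- tstat
  out$p.value <- 2 * stats::pt(-abs(tstat), df)
  class(out) <- "partial_corr"
  out
}

#' @export
print.partial_corr <- function(x, ...) {
  cat(sprintf("partial correlation (%s): r = %.4f, t(%d) = %.3f, p = %.4g, n = %d%s\n",
              x$method, x$estimate, x$df, x$statistic, x$p.value, x$n_used,
              if (x$status != "ok") paste0(" [", x$status, "]") else ""))
  invisible(x)
}

#' Shepherd's pi: robust partial correlation with bivariate outlier removal
#'
#' Residualizes `x` and `y` on `z`, standardizes both residual axes, computes
#' each point's L1 (Manhattan) distance from the coordinate-wise median of
#' the standardized residuals, and flags points whose distance exceeds the
#' `quantile` level of the empirical distance distribution. Pi is the
#' Spearman correlation of the retained residual pairs.
#'
#' @param x,y,z As in [partial_corr()].
#' @param quantile Distance quantile above which a point is flagged
#'   (default 0.99).
#' @param double_p Double the p-value (the convention of the original
#'   Shepherd's pi proposal); default FALSE, reporting the plain Spearman
#'   p-value on the retained points.
#' @return Object of class `partial_corr` with additional elements
#'   `outliers` (integer indices into the complete-case rows) and
#'   `distances`; `method` is `"shepherds_pi"`. `status = "degenerate"` when
#'   fewer than 4 points remain.
#' @export
shepherds_pi <- function(x, y, z, quantile = 0.99, double_p = FALSE) {
  ok <- is.finite(x) & is.finite(y) & is.finite(z)
  x <- x[ok]; y <- y[ok]; z <- z[ok]
  n <- length(x)
  if (n < 4) stop("Shepherd's pi needs n >= 4, got ", n)
  rx <- stats::lm.fit(cbind(1, z), x)$residuals
  ry <- stats::lm.fit(cbind(1, z), y)$residuals
  sx <- (rx - mean(rx)) / stats::sd(rx)
  sy <- (ry - mean(ry)) / stats::sd(ry)
  d <- abs(sx - stats::median(sx)) + abs(sy - stats::median(sy))
  cut <- stats::quantile(d, quantile, names = FALSE)
  flagged <- which(d > cut)
  keep <- setdiff(seq_len(n), flagged)
  out <- list(estimate = NA_real_, p.value = NA_real_, statistic = NA_real_,
              df = length(keep) - 3L, n_used = length(keep),
              method = "shepherds_pi", status = "ok",
              outliers = flagged, distances = d)
  if (length(keep) < 4) {
    out$status <- "degenerate"
    class(out) <- "partial_corr"
    return(out)
  }
  rho <- stats::cor(rx[keep], ry[keep], method = "spearman")
  df <- length(keep) - 3
  tstat <- rho * sqrt(df / max(1 - rho^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df)
  if (double_p) p <- min(1, 2 * p)
  out$estimate <- rho
  out$statistic <- tstat
  out$p.value <- p
  class(out) <- "partial_corr"
  out
}

#' Benjamini-Hochberg false discovery rate control
#'
#' Step-up adjusted p-values with enforced monotonicity, and significance
#' flags at level `q`.
#'
#' @param pvals Numeric vector of p-values in \[0, 1\].
#' @param q FDR level for the flags (default 0.05).
#' @return List with `adjusted` and `significant` (logical), both in the
#'   input order; empty inputs give empty outputs.
#' @export
bh_fdr <- function(pvals, q = 0.05) {
  if (length(pvals) == 0) {
    return(list(adjusted = numeric(0), significant = logical(0)))
  }
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]")
  }
  adj <- stats::p.adjust(pvals, method = "BH")
  list(adjusted = adj, significant = !is.na(adj) & adj <= q)
}

#' Univariate outlier prescreen (3 x IQR rule)
#'
#' Flags values lying more than `k` interquartile ranges beyond the
#' quartiles. Flags are reported only; nothing is removed.
#'
#' @param x Numeric vector.
#' @param k IQR multiplier (default 3).
#' @return Logical vector of flags.
#' @export
iqr_screen <- function(x, k = 3) {
  qs <- stats::quantile(x, c(0.25, 0.75), na.rm = TRUE, names = FALSE)
  iqr <- qs[2] - qs[1]
  !is.na(x) & (x < qs[1] - k * iqr | x > qs[2] + k * iqr)
}

#' Power density at the grid frequency nearest a target
#'
#' Nearest-neighbor extraction: the PSD value at the frequency bin with the
#' minimum absolute distance from the target. Ties between two equidistant
#' bins are broken toward the lower frequency.
#'
#' @param spec A `spectral_estimate`.
#' @param target_f Target frequency, Hz; must lie within the grid range.
#' @return PSD value at the nearest bin.
#' @export
nearest_bin_power <- function(spec, target_f) {
  f <- spec$frequency
  if (target_f < min(f) || target_f > max(f)) {
    stop(sprintf("target frequency %g Hz outside the spectral grid [%g, %g] Hz",
                 target_f, min(f), max(f)))
  }
  spec$psd[which.min(abs(f - target_f))]
}

#' Frequency-resolved partial-correlation curve across breathing periods
#'
#' For each breathing period on the grid (default 4 to 20 s, i.e. 0.25 down
#' to 0.05 Hz in 17 steps), extracts each subject's PSD at the nearest grid
#' frequency, natural-log transforms it, and computes the partial correlation
#' with post-intervention volume controlling for pre-intervention volume.
#' The 17 p-values are BH-FDR corrected as one family.
#'
#' @param spectra List of `spectral_estimate` objects, one per subject.
#' @param pre,post Numeric vectors of pre- and post-intervention volumes in
#'   the same subject order.
#' @param periods Breathing periods in seconds (default `4:20`).
#' @param q FDR level (default 0.05).
#' @param method Correlation method passed to [partial_corr()].
#' @return Data frame of class `correlation_curve`: `period_s`,
#'   `frequency_hz`, `r`, `p`, `p_adj`, `fdr_significant`, `n_used`.
#' @export
frequency_curve <- function(spectra, pre, post, periods = 4:20, q = 0.05,
                            method = "pearson") {
  stopifnot(length(spectra) == length(pre), length(pre) == length(post))
  if (length(pre) < 4) stop("need at least 4 subjects")
  rows <- lapply(periods, function(p_s) {
    f <- 1 / p_s
    pw <- vapply(spectra, function(s) {
      tryCatch(nearest_bin_power(s, f), error = function(e) NA_real_)
    }, numeric(1))
    lp <- log(pw)
    pc <- partial_corr(lp, post, pre, method = method)
    data.frame(period_s = p_s, frequency_hz = f, r = pc$estimate,
               p = pc$p.value, n_used = pc$n_used)
  })
  out <- do.call(rbind, rows)
  fdr <- bh_fdr(out$p, q = q)
  out$p_adj <- fdr$adjusted
  out$fdr_significant <- fdr$significant
  class(out) <- c("correlation_curve", "data.frame")
  out
}

#' Metric-by-ROI partial-correlation table
#'
#' Partial correlation of each HRV metric with post-intervention volume of
#' each ROI, controlling for the ROI's pre-intervention volume, with BH-FDR
#' applied over the whole grid (family scope configurable by correcting
#' subsets externally).
#'
#' @param metrics Data frame of subject-level HRV metrics (subjects in rows).
#' @param changes Data frame from [change_scores()] (long over ROIs), with
#'   subjects in the same order as `metrics` within each ROI.
#' @param metric_cols Character vector of metric column names to test.
#' @param q FDR level.
#' @param method Correlation method.
#' @return Data frame `roi_id`, `metric`, `r`, `p`, `p_adj`,
#'   `fdr_significant`, `n_used`.
#' @export
association_table <- function(metrics, changes, metric_cols, q = 0.05,
                              method = "pearson") {
  rows <- list()
  for (roi in unique(changes$roi_id)) {
    ch <- changes[changes$roi_id == roi, ]
    for (m in metric_cols) {
      pc <- partial_corr(metrics[[m]], ch$post, ch$pre, method = method)
      rows[[length(rows) + 1L]] <- data.frame(
        roi_id = roi, metric = m, r = pc$estimate, p = pc$p.value,
        n_used = pc$n_used)
    }
  }
  out <- do.call(rbind, rows)
  fdr <- bh_fdr(out$p, q = q)
  out$p_adj <- fdr$adjusted
  out$fdr_significant <- fdr$significant
  out
}
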