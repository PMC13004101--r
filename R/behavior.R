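#' P300 features from a stimulus-locked ERP waveform
#'
#' The waveform is re-referenced to its pre-stimulus baseline mean, the P300
#' amplitude is quantified as the trapezoidal area under the curve within the
#' component window, and the peak latency is the time of the maximum positive
#' local peak within that window. When the window contains no positive local
#' peak the latency is reported missing while the AUC is still returned.
#'
#' @param time Time in ms relative to stimulus onset (uniformly sampled,
#'   increasing).
#' @param amplitude Amplitude in microvolts.
#' @param window P300 window, ms (default `c(288, 432)`).
#' @param baseline Baseline window, ms (default `c(-200, 0)`).
#' @return List with `auc` (uV*ms) and `latency` (ms, `NA` if no peak).
#' @examples
#' t <- seq(-200, 800, by = 4)
#' w <- 5 * exp(-((t - 360) / 40)^2)
#' p300_features(t, w)
#' @export
p300_features <- function(time, amplitude, window = c(288, 432),
                          baseline = c(-200, 0)) {
  stopifnot(length(time) == length(amplitude))
  if (min(time) > baseline[1] || max(time) < window[2]) {
    stop("waveform must span the baseline and component windows")
  }
  bl <- mean(amplitude[time >= baseline[1] & time < baseline[2]])
  corrected <- amplitude - bl
  sel <- which(time >= window[1] & time <= window[2])
  tt <- time[sel]; aa <- corrected[sel]
  auc <- trapezoid(tt, aa)
  # positive local maxima strictly inside the window
  latency <- NA_real_
  if (length(sel) >= 3) {
    i <- 2:(length(sel) - 1)
    is_peak <- aa[i] > aa[i - 1] & aa[i] >= aa[i + 1] & aa[i] > 0
    if (any(is_peak)) {
      peaks <- i[is_peak]
      latency <- tt[peaks[which.max(aa[peaks])]]
    }
  }
  list(auc = auc, latency = latency)
}

# trapezoidal integral of y over x
trapezoid <- function(x, y) {
  n <- length(x)
  if (n < 2) return(0)
  sum(diff(x) * (y[-1] + y[-n]) / 2)
}

#' Pupil dilation response (PDR)
#'
#' Maximum change in pupil size relative to the mean of a pre-stimulus
#' baseline window, taken over the post-stimulus response window.
#'
#' @param time Time in ms relative to stimulus onset.
#' @param amplitude Pupil size (arbitrary units).
#' @param baseline_ms Baseline length before onset, ms (default 500; the
#'   baseline window is `[-baseline_ms, 0)`).
#' @param window_ms Response window after onset, ms (default 2000; the
#'   response window is `(0, window_ms]`).
#' @return Maximum baseline-corrected dilation (a.u.); `NA` when the response
#'   window holds no finite samples.
#' @export
pupil_pdr <- function(time, amplitude, baseline_ms = 500, window_ms = 2000) {
  stopifnot(length(time) == length(amplitude))
  if (min(time) > -baseline_ms || max(time) < window_ms) {
    stop("waveform must span the baseline and response windows")
  }
  bl <- mean(amplitude[time >= -baseline_ms & time < 0], na.rm = TRUE)
  resp <- amplitude[time > 0 & time <= window_ms]
  if (all(!is.finite(resp))) return(NA_real_)
  max(resp - bl, na.rm = TRUE)
}

#' Pre/post scores from binned game plays
#'
#' Raw per-play scores are standardized within each game across all
#' participants and plays; each participant's plays of a game are then split
#' in order into `n_bins` bins of (as near as possible) equal count, and the
#' pre and post scores are the means of the first and last bins.
#'
#' @param plays Data frame with columns `subject_id`, `game`, `play_index`,
#'   `score`.
#' @param n_bins Number of play bins (default 5).
#' @return Data frame `subject_id`, `game`, `pre`, `post`, `change`
#'   (z-units). Subject-game series with fewer than 2 plays are excluded.
#' @export
lumosity_bins <- function(plays, n_bins = 5) {
  need <- c("subject_id", "game", "play_index", "score")
  if (!all(need %in% names(plays))) {
    stop("plays must have columns ", paste(need, collapse = ", "))
  }
  plays$z <- stats::ave(plays$score, plays$game,
                        FUN = function(x) (x - mean(x)) / stats::sd(x))
  keys <- interaction(plays$subject_id, plays$game, drop = TRUE)
  rows <- lapply(split(plays, keys), function(d) {
    if (nrow(d) < 2) return(NULL)
    d <- d[order(d$play_index), ]
    bin <- ceiling(seq_len(nrow(d)) * n_bins / nrow(d))
    data.frame(subject_id = d$subject_id[1], game = d$game[1],
               pre = mean(d$z[bin == 1]), post = mean(d$z[bin == n_bins]))
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) return(data.frame())
  out <- do.call(rbind, rows)
  out$change <- out$post - out$pre
  rownames(out) <- NULL
  out
}

#' Z-score matrix columns
#'
#' @param M Numeric matrix (subjects x variables).
#' @return Matrix with each column centered and scaled to unit sample SD.
#' @export
zscore_columns <- function(M) {
  M <- as.matrix(M)
  scale(M)[, , drop = FALSE]
}

#' Build a z-scored change matrix from pre and post tables
#'
#' Computes post-minus-pre differences and z-scores each variable across
#' subjects. Missing cells are mean-imputed per column (with a message)
#' before z-scoring, so the matrix entering outlier screening is complete.
#'
#' @param pre,post Numeric matrices or data frames (subjects x variables)
#'   with matching dimensions and subject order.
#' @return Z-scored difference matrix of class `change_matrix`.
#' @export
change_matrix <- function(pre, post) {
  pre <- as.matrix(pre); post <- as.matrix(post)
  stopifnot(identical(dim(pre), dim(post)))
  d <- post - pre
  n_missing <- sum(!is.finite(d))
  if (n_missing > 0) {
    message(n_missing, " missing change cell(s) mean-imputed per column")
    for (j in seq_len(ncol(d))) {
      bad <- !is.finite(d[, j])
      d[bad, j] <- mean(d[!bad, j])
    }
  }
  out <- zscore_columns(d)
  class(out) <- c("change_matrix", class(out))
  out
}

#' Multivariate outlier screening by Mahalanobis distance
#'
#' Flags subjects whose squared Mahalanobis distance from the column-mean
#' vector (covariance by the usual n-1 estimator) exceeds the `1 - alpha`
#' quantile of the chi-square distribution with degrees of freedom equal to
#' the number of variables. Flagged rows are removed and the remaining rows
#' re-z-scored.
#'
#' @param M Numeric matrix (subjects x variables), typically a z-scored
#'   change matrix.
#' @param alpha Flagging level (default 0.01).
#' @return List with `flags` (logical per subject), `distances` (squared
#'   Mahalanobis distances), `threshold` (chi-square cutoff), and `cleaned`
#'   (flagged rows removed, columns re-z-scored).
#' @export
mahalanobis_screen <- function(M, alpha = 0.01) {
  M <- as.matrix(M)
  n <- nrow(M); p <- ncol(M)
  if (n <= p + 1) {
    stop(sprintf("need n_subjects > n_variables + 1 (n = %d, p = %d)", n, p))
  }
  S <- stats::cov(M)
  d2 <- tryCatch(
    stats::mahalanobis(M, colMeans(M), S),
    error = function(e) {
      stop("singular covariance matrix; reduce the variable set or ",
           "regularize before screening", call. = FALSE)
    }
  )
  threshold <- stats::qchisq(1 - alpha, df = p)
  flags <- d2 > threshold
  cleaned <- zscore_columns(M[!flags, , drop = FALSE])
  list(flags = flags, distances = d2, threshold = threshold,
       cleaned = cleaned)
}
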