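#' Partial least squares correlation: decomposition
#'
#' Singular value decomposition of the cross-block correlation matrix
#' `R = t(X) %*% Y / (n - 1)` between a brain change block `X` and a
#' behavioral change block `Y` (columns z-scored). Each latent variable (LV)
#' pairs a brain salience vector (left singular vector) with a behavioral
#' salience vector (right singular vector); latent scores are the projections
#' of the blocks onto their saliences. The sign of each LV is fixed by making
#' the largest-magnitude element of the behavioral salience positive.
#'
#' @param X,Y Numeric matrices with the same subjects in rows (and, when row
#'   names are present, identical row-name sets in the same order).
#' @param scale Z-score the columns of both blocks first (default TRUE; set
#'   FALSE when the inputs are already standardized or a raw cross-covariance
#'   decomposition is wanted).
#' @return Object of class `plsc`: list with `d` (singular values,
#'   nonincreasing), `u` (x saliences, columns unit norm), `v` (y saliences),
#'   `x_scores`, `y_scores` (subjects x LVs), `explained_variance` (% of
#'   squared singular value total per LV), `score_correlation` and
#'   `score_correlation_p` per LV, `n`, and the standardized blocks `X`, `Y`
#'   used for inference.
#' @examples
#' set.seed(1)
#' blocks <- simulate_change_blocks(sim_config(n_subjects = 20, n_x_vars = 6,
#'                                             n_y_vars = 4))
#' fit <- plsc_fit(blocks$X, blocks$Y)
#' fit$explained_variance
#' @export
plsc_fit <- function(X, Y, scale = TRUE) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (nrow(X) != nrow(Y)) {
    stop("X and Y must have the same number of subjects (rows): ",
         nrow(X), " vs ", nrow(Y))
  }
  if (!is.null(rownames(X)) && !is.null(rownames(Y)) &&
      !identical(rownames(X), rownames(Y))) {
    only_x <- setdiff(rownames(X), rownames(Y))
    only_y <- setdiff(rownames(Y), rownames(X))
    stop("mismatched subject sets; only in X: ",
         paste(only_x, collapse = ", "), "; only in Y: ",
         paste(only_y, collapse = ", "),
         if (length(only_x) + length(only_y) == 0)
           " (same ids, different order)" else "")
  }
  n <- nrow(X)
  if (n < 4) stop("PLSC needs n >= 4 subjects, got ", n)
  if (scale) {
    X <- zscore_columns(X)
    Y <- zscore_columns(Y)
  }
  R <- crossprod(X, Y) / (n - 1)
  sv <- svd(R)
  k <- length(sv$d)
  # sign convention: largest |element| of each y salience made positive
  for (j in seq_len(k)) {
    i <- which.max(abs(sv$v[, j]))
    if (sv$v[i, j] < 0) {
      sv$v[, j] <- -sv$v[, j]
      sv$u[, j] <- -sv$u[, j]
    }
  }
  x_scores <- X %*% sv$u
  y_scores <- Y %*% sv$v
  score_cor <- vapply(seq_len(k), function(j) {
    if (stats::sd(x_scores[, j]) == 0 || stats::sd(y_scores[, j]) == 0) {
      return(NA_real_)
    }
    stats::cor(x_scores[, j], y_scores[, j])
  }, numeric(1))
  score_p <- vapply(score_cor, function(r) {
    if (is.na(r)) return(NA_real_)
    tt <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
    2 * stats::pt(-abs(tt), n - 2)
  }, numeric(1))
  rownames(sv$u) <- colnames(X)
  rownames(sv$v) <- colnames(Y)
  colnames(sv$u) <- colnames(sv$v) <- paste0("LV", seq_len(k))
  colnames(x_scores) <- colnames(y_scores) <- paste0("LV", seq_len(k))
  structure(
    list(d = sv$d, u = sv$u, v = sv$v,
         x_scores = x_scores, y_scores = y_scores,
         explained_variance = 100 * sv$d^2 / sum(sv$d^2),
         score_correlation = score_cor, score_correlation_p = score_p,
         n = n, X = X, Y = Y, scaled = scale),
    class = "plsc"
  )
}

#' Permutation significance of PLSC latent variables
#'
#' The rows of `Y` are randomly shuffled `n_perm` times; each time the
#' cross-block singular values are recomputed. The p-value of the k-th LV is
#' the plain proportion of permuted k-th singular values exceeding the
#' observed one (per-rank comparison, no Procrustes re-alignment); an
#' add-one smoothed variant `(count + 1) / (n_perm + 1)` is available.
#'
#' @param fit A [plsc_fit()] result.
#' @param n_perm Number of permutations (default 5000; a warning is issued
#'   below 100).
#' @param seed Optional integer seed for reproducibility.
#' @param smoothed Use the add-one smoothed estimator (default FALSE).
#' @param procrustes Re-align each permuted decomposition to the observed
#'   saliences by orthogonal Procrustes rotation before reading off singular
#'   values (default FALSE).
#' @return Numeric vector of permutation p-values, one per LV.
#' @export
plsc_permutation <- function(fit, n_perm = 5000, seed = NULL,
                             smoothed = FALSE, procrustes = FALSE) {
  stopifnot(inherits(fit, "plsc"))
  if (n_perm < 100) {
    warning("n_perm = ", n_perm, " is low; permutation p-values are unstable")
  }
  if (!is.null(seed)) set.seed(seed)
  n <- fit$n
  k <- length(fit$d)
  exceed <- numeric(k)
  for (b in seq_len(n_perm)) {
    Yp <- fit$Y[sample.int(n), , drop = FALSE]
    Rp <- crossprod(fit$X, Yp) / (n - 1)
    dp <- if (procrustes) {
      # project the permuted cross-block matrix onto the observed singular
      # frame; read off per-LV magnitudes instead of re-sorted singular values
      abs(diag(crossprod(fit$u, Rp %*% fit$v)))
    } else {
      svd(Rp, nu = 0, nv = 0)$d
    }
    exceed <- exceed + (dp > fit$d)
  }
  if (smoothed) (exceed + 1) / (n_perm + 1) else exceed / n_perm
}

#' Bootstrap ratios for PLSC saliences
#'
#' Subjects are resampled with replacement (rows of `X` and `Y` jointly)
#' `n_boot` times; each resample is re-standardized and refit. Resampled
#' saliences are sign-aligned to the original solution per LV (by the sign of
#' the combined dot product with the original saliences, which maximizes it).
#' The bootstrap ratio (BSR) of each salience element is the original value
#' divided by the standard deviation of its aligned bootstrap distribution;
#' elements with |BSR| > `bsr_threshold` are flagged reliable.
#'
#' @param fit A [plsc_fit()] result.
#' @param n_boot Number of bootstrap resamples (default 5000).
#' @param seed Optional integer seed.
#' @param bsr_threshold Reliability threshold on |BSR| (default 1.96).
#' @return List with matrices `bsr_x`, `bsr_y` (variables x LVs),
#'   `significant_x`, `significant_y` (logical), `se_x`, `se_y` (bootstrap
#'   SDs) and `n_redrawn` (resamples redrawn because a column had zero
#'   variance).
#' @export
plsc_bootstrap <- function(fit, n_boot = 5000, seed = NULL,
                           bsr_threshold = 1.96) {
  stopifnot(inherits(fit, "plsc"))
  if (!is.null(seed)) set.seed(seed)
  n <- fit$n
  k <- length(fit$d)
  p <- nrow(fit$u); q <- nrow(fit$v)
  boot_u <- array(NA_real_, c(p, k, n_boot))
  boot_v <- array(NA_real_, c(q, k, n_boot))
  n_redrawn <- 0L
  for (b in seq_len(n_boot)) {
    repeat {
      idx <- sample.int(n, replace = TRUE)
      Xb <- fit$X[idx, , drop = FALSE]
      Yb <- fit$Y[idx, , drop = FALSE]
      sds <- c(apply(Xb, 2, stats::sd), apply(Yb, 2, stats::sd))
      if (all(sds > 0)) break
      n_redrawn <- n_redrawn + 1L
    }
    Rb <- crossprod(zscore_columns(Xb), zscore_columns(Yb)) / (n - 1)
    svb <- svd(Rb, nu = k, nv = k)
    for (j in seq_len(k)) {
      s <- sign(sum(svb$u[, j] * fit$u[, j]) + sum(svb$v[, j] * fit$v[, j]))
      if (s == 0) s <- 1
      boot_u[, j, b] <- s * svb$u[, j]
      boot_v[, j, b] <- s * svb$v[, j]
    }
  }
  se_x <- apply(boot_u, c(1, 2), stats::sd)
  se_y <- apply(boot_v, c(1, 2), stats::sd)
  bsr_x <- fit$u / se_x
  bsr_y <- fit$v / se_y
  dimnames(bsr_x) <- dimnames(fit$u)
  dimnames(bsr_y) <- dimnames(fit$v)
  list(bsr_x = bsr_x, bsr_y = bsr_y,
       significant_x = abs(bsr_x) > bsr_threshold,
       significant_y = abs(bsr_y) > bsr_threshold,
       se_x = se_x, se_y = se_y, n_redrawn = n_redrawn)
}

#' Full PLSC analysis with permutation and bootstrap inference
#'
#' Fits the decomposition, runs the permutation test, computes bootstrap
#' ratios, and adds per-variable Spearman loadings (correlation of each
#' behavioral variable with the brain latent scores).
#'
#' @param X,Y Subject x variable matrices (see [plsc_fit()]).
#' @param n_perm,n_boot Resampling sizes (defaults 5000).
#' @param seed Integer seed governing both resampling stages; required in
#'   strict mode.
#' @param scale Passed to [plsc_fit()].
#' @param strict Refuse to run without a seed (default TRUE).
#' @param ... Passed to [plsc_permutation()].
#' @return Object of class `plsc_result`: the [plsc_fit()] fields plus
#'   `perm_p`, `bsr_x`, `bsr_y`, `significant_x`, `significant_y`,
#'   `loading_rho`, `loading_rho_p` (behavioral variables x LVs), `n_perm`,
#'   `n_boot`, `seed`.
#' @export
plsc <- function(X, Y, n_perm = 5000, n_boot = 5000, seed = NULL,
                 scale = TRUE, strict = TRUE, ...) {
  if (is.null(seed) && strict) {
    stop("no seed supplied; set seed= (or strict = FALSE to use the ",
         "current RNG state)")
  }
  fit <- plsc_fit(X, Y, scale = scale)
  if (!is.null(seed)) set.seed(seed)
  perm_p <- plsc_permutation(fit, n_perm = n_perm, ...)
  boot <- plsc_bootstrap(fit, n_boot = n_boot)
  k <- length(fit$d)
  q <- ncol(fit$Y)
  loading_rho <- matrix(NA_real_, q, k,
                        dimnames = list(colnames(fit$Y),
                                        paste0("LV", seq_len(k))))
  loading_p <- loading_rho
  for (j in seq_len(k)) {
    for (m in seq_len(q)) {
      ct <- suppressWarnings(
        stats::cor.test(fit$Y[, m], fit$x_scores[, j], method = "spearman"))
      loading_rho[m, j] <- unname(ct$estimate)
      loading_p[m, j] <- ct$p.value
    }
  }
  out <- c(fit, list(perm_p = perm_p, bsr_x = boot$bsr_x,
                     bsr_y = boot$bsr_y,
                     significant_x = boot$significant_x,
                     significant_y = boot$significant_y,
                     n_redrawn = boot$n_redrawn,
                     loading_rho = loading_rho, loading_rho_p = loading_p,
                     n_perm = n_perm, n_boot = n_boot, seed = seed))
  class(out) <- c("plsc_result", "plsc")
  out
}

#' @export
print.plsc <- function(x, ...) {
  k <- length(x$d)
  cat("PLSC decomposition:", nrow(x$u), "x-variables,", nrow(x$v),
      "y-variables,", x$n, "subjects\n")
  tab <- data.frame(LV = seq_len(k),
                    singular_value = round(x$d, 4),
                    explained_pct = round(x$explained_variance, 1),
                    score_r = round(x$score_correlation, 3))
  if (!is.null(x$perm_p)) tab$perm_p <- signif(x$perm_p, 3)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Tabular and JSON report of a PLSC analysis
#'
#' @param result A `plsc_result` from [plsc()].
#' @param path Optional path; when given, the summary is written as JSON and
#'   the salience/BSR/score tables as TSV files alongside it
#'   (`<path>_saliences_x.tsv` etc.).
#' @param max_lv Number of LVs to report (default: all).
#' @return List with `summary` (per-LV data frame: singular value, explained
#'   variance, permutation p, score correlation and its p),
#'   `y_table` (per behavioral variable and LV: salience, BSR, reliability
#'   flag, Spearman loading and its p), `x_table` (same for x variables,
#'   without loadings), and `settings`.
#' @export
plsc_report <- function(result, path = NULL, max_lv = NULL) {
  stopifnot(inherits(result, "plsc_result"))
  k <- length(result$d)
  if (!is.null(max_lv)) k <- min(k, max_lv)
  lv <- seq_len(k)
  summary_df <- data.frame(
    lv = lv,
    singular_value = result$d[lv],
    explained_variance_pct = result$explained_variance[lv],
    perm_p = result$perm_p[lv],
    score_correlation = result$score_correlation[lv],
    score_correlation_p = result$score_correlation_p[lv]
  )
  y_table <- do.call(rbind, lapply(lv, function(j) {
    data.frame(lv = j, variable = rownames(result$v),
               salience = result$v[, j], bsr = result$bsr_y[, j],
               reliable = result$significant_y[, j],
               loading_rho = result$loading_rho[, j],
               loading_rho_p = result$loading_rho_p[, j],
               row.names = NULL)
  }))
  x_table <- do.call(rbind, lapply(lv, function(j) {
    data.frame(lv = j, variable = rownames(result$u),
               salience = result$u[, j], bsr = result$bsr_x[, j],
               reliable = result$significant_x[, j], row.names = NULL)
  }))
  settings <- list(n_subjects = result$n, n_perm = result$n_perm,
                   n_boot = result$n_boot, seed = result$seed,
                   scaled = result$scaled)
  rep <- list(summary = summary_df, y_table = y_table, x_table = x_table,
              settings = settings)
  if (!is.null(path)) {
    jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "columns")
    base <- sub("\\.json$", "", path)
    utils::write.table(y_table, paste0(base, "_saliences_y.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    utils::write.table(x_table, paste0(base, "_saliences_x.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }
  rep
}
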