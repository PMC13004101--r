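#' Breathing schedule for one 15-minute practice session
#'
#' A session consists of three 5-minute regimes, each paced at a fixed
#' breathing period. Slow-paced practice uses periods of 10, 12 or 15 s per
#' breath; random-paced practice uses 4, 5 or 6 s per breath.
#'
#' @param condition `"slow"` or `"random"`; selects the admissible pace set.
#' @param paces Optional numeric vector of exactly 3 breathing periods
#'   (seconds), one per regime. When `NULL`, three paces are drawn (with
#'   replacement) from the condition's admissible set using the current RNG.
#' @param session_duration Total session length in seconds (default 900 s,
#'   i.e. three 5-minute regimes).
#'
#' @return An object of class `breathing_schedule`: a list with elements
#'   `paces`, `condition`, `session_duration` and `regime_length`.
#' @examples
#' set.seed(1)
#' breathing_schedule("slow")
#' breathing_schedule("random", paces = c(4, 5, 6))
#' @export
breathing_schedule <- function(condition = c("slow", "random"), paces = NULL,
                               session_duration = 900) {
  condition <- match.arg(condition)
  admissible <- switch(condition, slow = c(10, 12, 15), random = c(4, 5, 6))
  if (is.null(paces)) {
    paces <- sample(admissible, 3L, replace = TRUE)
  }
  if (length(paces) != 3L) {
    stop("a session has exactly 3 regimes; supply 3 paces, got ", length(paces))
  }
  if (!all(paces %in% admissible)) {
    stop(sprintf("paces for the '%s' condition must lie in {%s}; got (%s)",
                 condition, paste(admissible, collapse = ", "),
                 paste(paces, collapse = ", ")))
  }
  if (session_duration <= 0) stop("session_duration must be positive")
  structure(
    list(paces = as.numeric(paces), condition = condition,
         session_duration = session_duration,
         regime_length = session_duration / 3),
    class = "breathing_schedule"
  )
}

#' Simulation configuration
#'
#' Bundles every tunable of the synthetic-data generator. Defaults describe a
#' realistic paced-breathing study: a resting heart period near 850 ms with
#' respiratory modulation of 80 ms peak amplitude, beat-to-beat noise of
#' 15 ms, a planted volume-change slope of 50 mm^3 per log-power unit against
#' measurement noise of 100 mm^3, and a single shared latent dimension of
#' strength 0.8 linking a 50-column brain-change block to an 8-column
#' behavioral-change block.
#'
#' @param n_subjects Number of subjects.
#' @param base_ibi Mean inter-beat interval, ms.
#' @param modulation_depth Peak amplitude of the breathing-paced modulation of
#'   the heart period, ms. Must be below `base_ibi / 2`.
#' @param ibi_noise_sd SD of Gaussian beat-to-beat noise, ms.
#' @param planted_slope Planted dependence of volume change on log band
#'   power, mm^3 per log-power unit.
#' @param volume_noise_sd SD of Gaussian volume measurement noise, mm^3.
#' @param latent_strength Strength of the single shared latent dimension
#'   between the change blocks, in \[0, 1\].
#' @param n_x_vars,n_y_vars Number of columns of the brain (X) and behavioral
#'   (Y) change blocks.
#' @param block_noise_sd SD of the independent Gaussian noise added to each
#'   change-block cell.
#' @param baseline_volume,baseline_volume_sd Mean and SD of pre-intervention
#'   ROI volumes, mm^3.
#' @param icv_mean,icv_sd Mean and SD of intracranial volume, mm^3.
#' @param scan_times Scan times of the three timepoints, years from baseline.
#' @param seed Integer seed; the same configuration and seed reproduce the
#'   generated data exactly.
#'
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_subjects = 55, base_ibi = 850, modulation_depth = 80,
                       ibi_noise_sd = 15, planted_slope = 50,
                       volume_noise_sd = 100, latent_strength = 0.8,
                       n_x_vars = 50, n_y_vars = 8, block_noise_sd = 0.25,
                       baseline_volume = 7000, baseline_volume_sd = 400,
                       icv_mean = 1.5e6, icv_sd = 1.2e5,
                       scan_times = c(0, 0.44, 0.85), seed = 1L) {
  stopifnot(n_subjects >= 1, base_ibi > 0)
  sds <- c(ibi_noise_sd = ibi_noise_sd, volume_noise_sd = volume_noise_sd,
           block_noise_sd = block_noise_sd,
           baseline_volume_sd = baseline_volume_sd, icv_sd = icv_sd)
  if (any(sds < 0)) {
    stop("negative SD: ", paste(names(sds)[sds < 0], collapse = ", "))
  }
  if (latent_strength < 0 || latent_strength > 1) {
    stop("latent_strength must lie in [0, 1], got ", latent_strength)
  }
  if (modulation_depth < 0) stop("modulation_depth must be >= 0")
  structure(
    list(n_subjects = as.integer(n_subjects), base_ibi = base_ibi,
         modulation_depth = modulation_depth, ibi_noise_sd = ibi_noise_sd,
         planted_slope = planted_slope, volume_noise_sd = volume_noise_sd,
         latent_strength = latent_strength, n_x_vars = as.integer(n_x_vars),
         n_y_vars = as.integer(n_y_vars), block_noise_sd = block_noise_sd,
         baseline_volume = baseline_volume,
         baseline_volume_sd = baseline_volume_sd,
         icv_mean = icv_mean, icv_sd = icv_sd, scan_times = scan_times,
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' Simulate an inter-beat-interval series for one paced-breathing session
#'
#' Generates beat times by an integrate-and-fire rule on the instantaneous
#' heart period: the next beat occurs one current period after the previous
#' beat, where the current period is
#' `base_ibi + modulation_depth * sin(2*pi*t / pace) + noise` and the pace
#' switches instantaneously at regime boundaries.
#'
#' @param schedule A [breathing_schedule()].
#' @param config A [sim_config()]; `modulation_depth`, `base_ibi` and
#'   `ibi_noise_sd` are used. Draws from the current RNG state.
#'
#' @return A data frame of class `ibi_series` with columns `beat_time_s`
#'   (seconds from session start, strictly increasing) and `ibi_ms`.
#' @examples
#' set.seed(2)
#' ibi <- simulate_ibi(breathing_schedule("slow", paces = c(10, 12, 15)),
#'                     sim_config(ibi_noise_sd = 5))
#' head(ibi)
#' @export
simulate_ibi <- function(schedule, config) {
  stopifnot(inherits(schedule, "breathing_schedule"),
            inherits(config, "sim_config"))
  if (config$modulation_depth >= config$base_ibi / 2) {
    stop(sprintf(
      "modulation_depth (%g ms) must be below base_ibi/2 (%g ms)",
      config$modulation_depth, config$base_ibi / 2))
  }
  dur <- schedule$session_duration
  reg_len <- schedule$regime_length
  # ~dur / (base_ibi/1000) beats expected; pad generously
  n_max <- ceiling(dur / (config$base_ibi / 1000) * 2) + 16L
  beat_time <- numeric(n_max)
  ibi <- numeric(n_max)
  t <- 0
  i <- 0L
  while (t < dur && i < n_max) {
    regime <- min(3L, floor(t / reg_len) + 1L)
    pace <- schedule$paces[regime]
    period <- config$base_ibi +
      config$modulation_depth * sin(2 * pi * t / pace) +
      (if (config$ibi_noise_sd > 0) stats::rnorm(1, 0, config$ibi_noise_sd) else 0)
    if (period <= 0) {
      stop(sprintf(
        paste0("non-positive IBI generated (%.1f ms) at t = %.1f s: ",
               "modulation_depth = %g ms plus ibi_noise_sd = %g ms is too ",
               "large for base_ibi = %g ms"),
        period, t, config$modulation_depth, config$ibi_noise_sd,
        config$base_ibi))
    }
    t <- t + period / 1000
    i <- i + 1L
    beat_time[i] <- t
    ibi[i] <- period
  }
  out <- data.frame(beat_time_s = beat_time[seq_len(i)],
                    ibi_ms = ibi[seq_len(i)])
  class(out) <- c("ibi_series", "data.frame")
  out
}

#' Simulate a three-timepoint longitudinal volume panel
#'
#' Pre-intervention volumes are drawn from a Gaussian baseline distribution;
#' post-intervention volume adds a planted linear dependence on the supplied
#' (mean-centered) log band power plus noise; the mid-timepoint is the
#' average of pre and post plus noise. Intracranial volume is generated
#' independently and carried as a covariate column.
#'
#' @param log_power Numeric vector, one log band-power value per subject.
#' @param config A [sim_config()].
#' @param roi_id ROI label for the panel (single ROI per call).
#'
#' @return A long-format data frame (class `volume_panel`) with columns
#'   `subject_id`, `roi_id`, `timepoint` (`pre`/`mid`/`post`), `volume_mm3`,
#'   `scan_time_y`, `icv_mm3`.
#' @export
simulate_volume_panel <- function(log_power, config, roi_id = "left_medial_ofc") {
  stopifnot(inherits(config, "sim_config"))
  n <- length(log_power)
  if (n < 4) {
    stop("need at least 4 subjects (got ", n,
         "); downstream partial correlation is undefined below n = 4")
  }
  if (anyNA(log_power)) stop("log_power contains missing values")
  pre <- stats::rnorm(n, config$baseline_volume, config$baseline_volume_sd)
  post <- pre + config$planted_slope * (log_power - mean(log_power)) +
    stats::rnorm(n, 0, config$volume_noise_sd)
  mid <- (pre + post) / 2 + stats::rnorm(n, 0, config$volume_noise_sd)
  icv <- stats::rnorm(n, config$icv_mean, config$icv_sd)
  subj <- sprintf("sub-%03d", seq_len(n))
  out <- data.frame(
    subject_id = rep(subj, times = 3),
    roi_id = roi_id,
    timepoint = rep(c("pre", "mid", "post"), each = n),
    volume_mm3 = c(pre, mid, post),
    scan_time_y = rep(config$scan_times, each = n),
    icv_mm3 = rep(icv, times = 3)
  )
  class(out) <- c("volume_panel", "data.frame")
  out
}

#' Simulate paired change blocks sharing one planted latent dimension
#'
#' Builds subject-by-variable matrices `X` (brain change) and `Y` (behavioral
#' change) as `latent_strength * s %o% u + noise` and
#' `latent_strength * s %o% v + noise`, where `s` are standard-normal subject
#' scores and `u`, `v` are fixed unit salience vectors. The planted structure
#' is attached as attributes so recovery can be measured.
#'
#' @param config A [sim_config()]; uses `n_subjects`, `n_x_vars`, `n_y_vars`,
#'   `latent_strength` and `block_noise_sd`. Draws from the current RNG state.
#'
#' @return A list with matrices `X` (`n_subjects` x `n_x_vars`) and `Y`
#'   (`n_subjects` x `n_y_vars`), each carrying attributes `planted_salience`
#'   (the generator's unit weight vector), `planted_salience_std` (the
#'   population salience after column standardization, i.e. the normalized
#'   vector of per-column correlations with the latent score -- the estimand
#'   of a PLSC run on z-scored columns) and `planted_scores` (`s`). Row
#'   names are subject ids.
#' @export
simulate_change_blocks <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_subjects
  p <- config$n_x_vars
  q <- config$n_y_vars
  s <- stats::rnorm(n)
  u <- stats::rnorm(p); u <- u / sqrt(sum(u^2))
  v <- stats::rnorm(q); v <- v / sqrt(sum(v^2))
  X <- config$latent_strength * tcrossprod(s, u) +
    matrix(stats::rnorm(n * p, 0, config$block_noise_sd), n, p)
  Y <- config$latent_strength * tcrossprod(s, v) +
    matrix(stats::rnorm(n * q, 0, config$block_noise_sd), n, q)
  subj <- sprintf("sub-%03d", seq_len(n))
  dimnames(X) <- list(subj, sprintf("vertex_%03d", seq_len(p)))
  dimnames(Y) <- list(subj, sprintf("measure_%02d", seq_len(q)))
  # population salience on the standardized scale: column j of the z-scored
  # block correlates with s in proportion to a*w_j / sd_j
  std_sal <- function(w) {
    a <- config$latent_strength
    sj <- sqrt((a * w)^2 + config$block_noise_sd^2)
    out <- (a * w) / sj
    nrm <- sqrt(sum(out^2))
    if (nrm > 0) out / nrm else out
  }
  attr(X, "planted_salience") <- u
  attr(Y, "planted_salience") <- v
  attr(X, "planted_salience_std") <- std_sal(u)
  attr(Y, "planted_salience_std") <- std_sal(v)
  attr(X, "planted_scores") <- s
  attr(Y, "planted_scores") <- s
  list(X = X, Y = Y)
}

#' Write an IBI series to CSV
#'
#' @param series An `ibi_series` data frame.
#' @param path Output file path. A JSON sidecar `<path>.json` records `config`
#'   when supplied.
#' @param config Optional [sim_config()] recorded alongside the data.
#' @return `path`, invisibly.
#' @export
write_ibi_csv <- function(series, path, config = NULL) {
  utils::write.csv(as.data.frame(series)[, c("beat_time_s", "ibi_ms")],
                   path, row.names = FALSE, quote = FALSE)
  if (!is.null(config)) {
    jsonlite::write_json(unclass(config), paste0(path, ".json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read an IBI series from CSV
#'
#' @param path CSV with columns `beat_time_s`, `ibi_ms`.
#' @return An `ibi_series` data frame.
#' @export
read_ibi_csv <- function(path) {
  x <- utils::read.csv(path)
  if (!all(c("beat_time_s", "ibi_ms") %in% names(x))) {
    stop("expected columns beat_time_s, ibi_ms in ", path)
  }
  if (is.unsorted(x$beat_time_s, strictly = TRUE)) {
    stop("beat_time_s must be strictly increasing in ", path)
  }
  if (any(x$ibi_ms <= 0)) stop("ibi_ms must be positive in ", path)
  class(x) <- c("ibi_series", "data.frame")
  x
}
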