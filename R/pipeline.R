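#' Default pipeline configuration
#'
#' Configuration for the end-to-end synthetic-study workflow: simulate IBI
#' sessions, compute HRV metrics, simulate a planted volume panel, run the
#' association analyses, and fit PLSC on planted change blocks. Every
#' threshold that affects results lives here and is echoed into the output
#' manifest.
#'
#' @param seed Master seed; all stage seeds are derived from it.
#' @param n_subjects Number of simulated subjects.
#' @param sessions_per_subject Simulated practice sessions per subject
#'   (default 3; kept small since regime metrics are averaged anyway).
#' @param condition Breathing condition for the simulated sessions.
#' @param n_perm,n_boot PLSC resampling sizes.
#' @param fdr_q FDR level for association tables.
#' @param out_dir Output directory (`NULL` = do not write files).
#' @param sim Overrides passed to [sim_config()] (a named list).
#' @param bands Band definition (default [hrv_bands()]).
#' @return Named list of class `run_config`.
#' @export
run_config <- function(seed = 1L, n_subjects = 55, sessions_per_subject = 3,
                       condition = "slow", n_perm = 1000, n_boot = 1000,
                       fdr_q = 0.05, out_dir = NULL, sim = list(),
                       bands = hrv_bands()) {
  cfg <- c(list(n_subjects = n_subjects, seed = seed), sim)
  structure(
    list(seed = as.integer(seed), n_subjects = n_subjects,
         sessions_per_subject = sessions_per_subject, condition = condition,
         n_perm = n_perm, n_boot = n_boot, fdr_q = fdr_q, out_dir = out_dir,
         sim = do.call(sim_config, cfg), bands = bands),
    class = "run_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the arguments of [run_config()]; a `sim` mapping
#' holds [sim_config()] overrides.
#'
#' @param path YAML file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  y <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  unknown <- setdiff(names(y), known)
  if (length(unknown)) {
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  }
  do.call(run_config, y)
}

#' Run the full synthetic-study pipeline
#'
#' Stages, in dependency order: (1) simulate paced-breathing IBI sessions per
#' subject and reduce them to subject-level HRV metrics; (2) simulate a
#' three-timepoint volume panel whose change is planted on log upper-LF
#' power; (3) metric-by-ROI partial-correlation table with BH-FDR and the
#' frequency-resolved correlation curve; (4) simulate planted change blocks
#' and run PLSC with permutation and bootstrap inference. All randomness
#' derives from the master seed, so identical configurations reproduce
#' identical bundles. When `out_dir` is set, each table is written as TSV and
#' a `MANIFEST.json` records the configuration, seed and package version.
#'
#' @param config A `run_config` (or path to a YAML file readable by
#'   [read_run_config()]).
#' @return Invisibly, a list with `metrics`, `panel`, `assoc_table`, `curve`,
#'   `plsc`, `report`, and `manifest`.
#' @export
run_pipeline <- function(config = run_config()) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  sim <- config$sim
  set.seed(config$seed)

  # stage 1: IBI simulation + HRV reduction
  subjects <- sprintf("sub-%03d", seq_len(config$n_subjects))
  metrics <- vector("list", config$n_subjects)
  spectra <- vector("list", config$n_subjects)
  for (i in seq_len(config$n_subjects)) {
    recs <- list()
    best <- NULL
    for (s in seq_len(config$sessions_per_subject)) {
      sched <- breathing_schedule(config$condition)
      ibi <- simulate_ibi(sched, sim)
      recs[[s]] <- session_metrics(ibi, bands = config$bands)
      if (is.null(best)) {
        seg1 <- segment_session(clean_ibi(ibi))[[1]]
        if (seg1$included) {
          best <- spectral_power(interpolate_hr(seg1),
                                 bands = config$bands)$spectrum
        }
      }
    }
    metrics[[i]] <- aggregate_subject(do.call(rbind, recs))
    spectra[[i]] <- best
  }
  metrics <- cbind(subject_id = subjects, do.call(rbind, metrics))

  # stage 2: planted volume panel
  panel <- simulate_volume_panel(metrics$log_upper_lf, sim)
  changes <- change_scores(panel)

  # stage 3: associations
  metric_cols <- grep("^log_", names(metrics), value = TRUE)
  assoc <- association_table(metrics, changes, metric_cols, q = config$fdr_q)
  curve <- frequency_curve(spectra, changes$pre, changes$post,
                           q = config$fdr_q)

  # stage 4: planted change blocks + PLSC
  blocks <- simulate_change_blocks(sim)
  fit <- plsc(blocks$X, blocks$Y, n_perm = config$n_perm,
              n_boot = config$n_boot, seed = config$seed)
  report <- plsc_report(fit)

  manifest <- list(
    package = "hrvofc",
    version = as.character(utils::packageVersion("hrvofc")),
    seed = config$seed,
    n_subjects = config$n_subjects,
    sessions_per_subject = config$sessions_per_subject,
    condition = config$condition,
    n_perm = config$n_perm, n_boot = config$n_boot, fdr_q = config$fdr_q,
    sim = unclass(sim),
    bands = config$bands
  )

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    wt <- function(x, name) {
      utils::write.table(x, file.path(config$out_dir, name), sep = "\t",
                         row.names = FALSE, quote = FALSE)
    }
    wt(metrics, "hrv_metrics.tsv")
    write_volume_panel(panel, file.path(config$out_dir, "volume_panel.tsv"))
    wt(assoc, "association_table.tsv")
    wt(as.data.frame(curve), "frequency_curve.tsv")
    plsc_report(fit, path = file.path(config$out_dir, "plsc_report.json"))
    jsonlite::write_json(manifest, file.path(config$out_dir, "MANIFEST.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  invisible(list(metrics = metrics, panel = panel, assoc_table = assoc,
                 curve = curve, plsc = fit, report = report,
                 manifest = manifest))
}
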