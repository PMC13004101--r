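#' Symmetrized percent change (SPC)
#'
#' Annualized rate of volume change relative to the mean volume across the
#' available timepoints: `100 * slope / mean(volumes)`, with the slope from
#' an ordinary least-squares fit of volume on scan time. With exactly two
#' timepoints this reduces to the two-point difference quotient.
#'
#' @param volumes Numeric vector of volumes (mm^3), one per timepoint.
#' @param times Scan times in years from baseline; defaults to the protocol
#'   weeks 2/7/12 expressed in years.
#' @return SPC in percent per year.
#' @examples
#' spc(c(1000, 1050, 1100), times = c(0, 0.5, 1))  # 9.5238 %/y
#' @export
spc <- function(volumes, times = c(0, 0.44, 0.85)) {
  if (length(volumes) != length(times)) {
    stop("volumes and times must have equal length")
  }
  ok <- is.finite(volumes) & is.finite(times)
  volumes <- volumes[ok]; times <- times[ok]
  if (length(unique(times)) < 2) {
    stop("SPC undefined: need at least 2 distinct scan times")
  }
  slope <- stats::cov(times, volumes) / stats::var(times)
  100 * slope / mean(volumes)
}

#' Per-subject change scores from a longitudinal volume panel
#'
#' Tidy table of pre, post and post-minus-pre volume per subject and ROI.
#' Subject-ROI pairs missing either the pre or the post timepoint are dropped
#' with a message; a missing mid timepoint is tolerated (it does not enter
#' the difference).
#'
#' @param panel A long-format `volume_panel` data frame with columns
#'   `subject_id`, `roi_id`, `timepoint`, `volume_mm3`.
#' @return Data frame with columns `subject_id`, `roi_id`, `pre`, `post`,
#'   `change` (mm^3).
#' @export
change_scores <- function(panel) {
  need <- c("subject_id", "roi_id", "timepoint", "volume_mm3")
  if (!all(need %in% names(panel))) {
    stop("panel must have columns ", paste(need, collapse = ", "))
  }
  wide <- stats::reshape(
    panel[panel$timepoint %in% c("pre", "post"),
          c("subject_id", "roi_id", "timepoint", "volume_mm3")],
    idvar = c("subject_id", "roi_id"), timevar = "timepoint",
    direction = "wide"
  )
  names(wide) <- sub("^volume_mm3\\.", "", names(wide))
  for (tp in c("pre", "post")) if (!tp %in% names(wide)) wide[[tp]] <- NA_real_
  complete <- !is.na(wide$pre) & !is.na(wide$post)
  if (any(!complete)) {
    message(sum(!complete),
            " subject-ROI pair(s) dropped: missing pre or post volume")
  }
  out <- wide[complete, c("subject_id", "roi_id", "pre", "post")]
  out$change <- out$post - out$pre
  rownames(out) <- NULL
  out
}

#' SPC per subject and ROI from a volume panel
#'
#' @param panel A `volume_panel` with `scan_time_y` present.
#' @return Data frame `subject_id`, `roi_id`, `spc` (percent per year).
#' @export
spc_table <- function(panel) {
  keys <- interaction(panel$subject_id, panel$roi_id, drop = TRUE)
  rows <- lapply(split(panel, keys), function(d) {
    data.frame(subject_id = d$subject_id[1], roi_id = d$roi_id[1],
               spc = spc(d$volume_mm3, d$scan_time_y))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read / write long-format volume panels
#'
#' TSV with columns `subject_id`, `roi_id`, `timepoint`, `volume_mm3`,
#' `scan_time_y`, `icv_mm3`.
#'
#' @param path File path.
#' @return `read_volume_panel`: a `volume_panel` data frame.
#' @export
read_volume_panel <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (any(x$volume_mm3 <= 0, na.rm = TRUE)) stop("volumes must be positive")
  class(x) <- c("volume_panel", "data.frame")
  x
}

#' @rdname read_volume_panel
#' @param panel Panel to write.
#' @export
write_volume_panel <- function(panel, path) {
  utils::write.table(as.data.frame(panel), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
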