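# Per-subject summary: median (prefix m) and IQR (prefix v) of every
# per-breath parameter over a recording. Quartiles use linear interpolation
# of order statistics at positions 1 + 0.25(n-1) and 1 + 0.75(n-1)
# (quantile type 7), fixed so that results are bit-stable.

summary_params <- c("rr", "tI", "tE", "tTot", "tI_over_tE", "tI_over_tTot",
                    "ptif", "ptef", "tptif_over_tI", "tptef_over_tE",
                    "tif50", "tef50", "ie50", "rct", "taa_deg", "hta_deg")

#' Summarize a subject's breath records into m/v values
#'
#' For each parameter `P`, reports `m_P` (the median across valid breaths)
#' and `v_P` (the interquartile range, a robust within-subject variability
#' measure). Parameters missing in some breaths are summarized over the
#' breaths where they are available.
#'
#' @param records per-breath parameter table ([breath_table()] output).
#' @param subject_id,group_label identifiers carried into the summary; taken
#'   from `records` when omitted.
#' @return one-row data frame: `subject_id`, `group_label`, `n_breaths`,
#'   then `m_<param>` and `v_<param>` columns.
#' @export
summarize_subject <- function(records, subject_id = NULL,
                              group_label = NA_character_) {
  if (nrow(records) < 2) stop("insufficient breaths: need >= 2 valid records")
  if (is.null(subject_id))
    subject_id <- if ("subject_id" %in% names(records))
      records$subject_id[1] else NA_character_
  out <- data.frame(subject_id = subject_id, group_label = group_label,
                    n_breaths = nrow(records))
  for (p in intersect(summary_params, names(records))) {
    v <- records[[p]][!is.na(records[[p]])]
    out[[paste0("m_", p)]] <- if (length(v)) stats::median(v) else NA_real_
    out[[paste0("v_", p)]] <- if (length(v) >= 2)
      stats::IQR(v, type = 7) else NA_real_
  }
  out
}

#' Count valid breath records
#'
#' @param x either a per-breath record table (all rows counted) or a
#'   detection table carrying a `valid` flag column (valid rows counted).
#' @return integer count.
#' @export
count_valid_breaths <- function(x) {
  if ("valid" %in% names(x)) sum(x$valid) else nrow(x)
}

#' Analyze one displacement recording end to end
#'
#' Runs the full single-recording pipeline: artifact detection, breath
#' detection, breath-level exclusion rules, the recording-level quality gate,
#' and per-breath parameter extraction for the valid breaths.
#'
#' @param trace a [displacement_trace()] (or an `slp_recording`, whose trace
#'   is used).
#' @param subject_id identifier attached to the outputs.
#' @param group_label optional cohort label.
#' @param K extreme-duration multiplier passed to [filter_breaths()].
#' @return an object of class `slp_analysis`: list with `breaths` (detection
#'   table with flags), `artifacts`, `records` (per-breath parameters, valid
#'   breaths only), `quality` (from [assess_recording()]), `trace`,
#'   `subject_id`, `group_label`.
#' @export
slp_analyze <- function(trace, subject_id = "subject", group_label = NA,
                        K = 5) {
  if (inherits(trace, "slp_recording")) {
    if (is.na(group_label)) group_label <- trace$spec$group_label
    trace <- trace$trace
  }
  stopifnot(inherits(trace, "displacement_trace"))
  artifacts <- detect_artifacts(trace)
  breaths <- suppressWarnings(detect_breaths(trace))
  breaths <- filter_breaths(breaths, artifacts, K = K)
  quality <- assess_recording(breaths)
  records <- if (quality$accepted)
    breath_table(trace, breaths, subject_id = subject_id)
  else breath_table(trace, breaths[0, , drop = FALSE],
                    subject_id = subject_id)
  structure(list(breaths = breaths, artifacts = artifacts, records = records,
                 quality = quality, trace = trace, subject_id = subject_id,
                 group_label = group_label),
            class = "slp_analysis")
}

#' @export
print.slp_analysis <- function(x, ...) {
  cat(sprintf("<slp_analysis> subject %s: %d breaths detected, %d valid\n",
              x$subject_id, nrow(x$breaths), sum(x$breaths$valid)))
  cat(sprintf("  quality: %s (%s)\n",
              if (x$quality$accepted) "accepted" else "REJECTED",
              x$quality$reason))
  if (nrow(x$records) > 0)
    cat(sprintf("  median IE50 %.3f, median tI/tE %.3f, median RR %.1f brpm\n",
                stats::median(x$records$ie50, na.rm = TRUE),
                stats::median(x$records$tI_over_tE, na.rm = TRUE),
                stats::median(x$records$rr, na.rm = TRUE)))
  invisible(x)
}

#' @export
summary.slp_analysis <- function(object, ...) {
  if (!object$quality$accepted)
    stop("recording rejected by quality gate: ", object$quality$reason)
  summarize_subject(object$records, subject_id = object$subject_id,
                    group_label = object$group_label)
}

#' @export
plot.slp_analysis <- function(x, ...) {
  graphics::plot(x$trace$time, x$trace$channels$total, type = "l",
                 xlab = "time (s)", ylab = "TA displacement (a.u.)", ...)
  ok <- x$breaths$valid
  graphics::points(x$breaths$peak_time[ok],
                   x$trace$channels$total[x$breaths$peak_index[ok]],
                   col = "forestgreen", pch = 20)
  graphics::points(x$breaths$peak_time[!ok],
                   x$trace$channels$total[x$breaths$peak_index[!ok]],
                   col = "red", pch = 4)
  if (nrow(x$artifacts) > 0)
    graphics::rect(x$artifacts$start_time,
                   graphics::par("usr")[3],
                   x$artifacts$end_time, graphics::par("usr")[4],
                   col = grDevices::adjustcolor("orange", 0.2), border = NA)
  invisible(x)
}

#' Summarize a whole cohort of recordings
#'
#' Convenience wrapper: analyzes each recording and stacks the accepted
#' subjects' summary rows. Rejected recordings are dropped with their reason
#' recorded in the `rejected` attribute.
#'
#' @param recordings list of `slp_recording` or `displacement_trace`.
#' @param subject_ids character vector of ids (defaults to positions).
#' @param group_label cohort label for all subjects.
#' @return data frame of per-subject summaries (see [summarize_subject()]).
#' @export
summarize_cohort <- function(recordings, subject_ids = NULL,
                             group_label = NA) {
  if (is.null(subject_ids))
    subject_ids <- sprintf("s%02d", seq_along(recordings))
  rows <- list(); rej <- list()
  for (i in seq_along(recordings)) {
    a <- slp_analyze(recordings[[i]], subject_id = subject_ids[i],
                     group_label = group_label)
    if (a$quality$accepted && nrow(a$records) >= 2)
      rows[[length(rows) + 1]] <- summary(a)
    else rej[[subject_ids[i]]] <- a$quality$reason
  }
  out <- if (length(rows)) do.call(rbind, rows) else data.frame()
  attr(out, "rejected") <- rej
  out
}
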