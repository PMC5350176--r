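# Per-breath tidal breathing parameters: timing indices, displacement-rate
# parameters, flow-shape loop indices, regional contribution and Konno-Mead
# phase. All operate on one breath (a row of the detection table) plus the
# displacement / displacement-rate signals of the recording.

breath_span <- function(breath) breath$start_index:breath$end_index

#' Timing indices of one breath
#'
#' @param breath one row of the [detect_breaths()] table.
#' @param trace the [displacement_trace()] the breath was detected in.
#' @return list with `tI`, `tE`, `tTot` (s), `rr` (breaths/min),
#'   `tI_over_tE`, `tI_over_tTot`.
#' @export
compute_timing <- function(breath, trace) {
  # use the sub-sample refined boundary times when the detection table
  # carries them, sample times otherwise
  s <- if (!is.null(breath$start_time)) breath$start_time
       else trace$time[breath$start_index]
  p <- if (!is.null(breath$peak_time)) breath$peak_time
       else trace$time[breath$peak_index]
  e <- if (!is.null(breath$end_time)) breath$end_time
       else trace$time[breath$end_index]
  if (p <= s || e <= p) stop("degenerate breath: peak at boundary")
  tI <- p - s
  tE <- e - p
  list(tI = tI, tE = tE, tTot = tI + tE, rr = 60 / (tI + tE),
       tI_over_tE = tI / tE, tI_over_tTot = tI / (tI + tE))
}

#' Peak displacement-rate parameters of one breath
#'
#' PTIF and PTEF are the peak inspiratory and expiratory displacement-rate
#' magnitudes over their limbs; the times to reach them are measured from the
#' limb onset and normalized by the limb duration.
#'
#' @param breath one detection-table row.
#' @param trace the trace.
#' @param rate displacement-rate signal of the total channel
#'   (from [compute_rate()]).
#' @return list with `ptif`, `ptef` (a.u./s, magnitudes), `tptif_over_tI`,
#'   `tptef_over_tE`.
#' @export
compute_rate_params <- function(breath, trace, rate) {
  ins <- breath$start_index:breath$peak_index
  exp_ <- breath$peak_index:breath$end_index
  if (all(rate[ins] == 0) || all(rate[exp_] == 0))
    stop("all-zero displacement rate over a limb")
  i_max <- ins[which.max(rate[ins])]
  e_max <- exp_[which.min(rate[exp_])]
  tI <- trace$time[breath$peak_index] - trace$time[breath$start_index]
  tE <- trace$time[breath$end_index] - trace$time[breath$peak_index]
  clamp01 <- function(v) max(min(v, 1), 1 / (2 * length(rate)))
  list(ptif = abs(rate[i_max]), ptef = abs(rate[e_max]),
       tptif_over_tI =
         clamp01((trace$time[i_max] - trace$time[breath$start_index]) / tI),
       tptef_over_tE =
         clamp01((trace$time[e_max] - trace$time[breath$peak_index]) / tE))
}

# first crossing of `level` by x over index window idx; returns interpolated
# time, or NA if the limb never crosses
first_crossing_time <- function(x, time, idx, level) {
  v <- x[idx] - level
  j <- which(v[-length(v)] * v[-1] <= 0 & v[-length(v)] != v[-1])
  if (!length(j)) {
    z <- which(v == 0)
    if (length(z)) return(time[idx[z[1]]])
    return(NA_real_)
  }
  j <- j[1]
  i0 <- idx[j]; i1 <- idx[j + 1]
  f <- (level - x[i0]) / (x[i1] - x[i0])
  time[i0] + f * (time[i1] - time[i0])
}

interp_at <- function(time, y, t) stats::approx(time, y, xout = t)$y

#' Flow-shape loop indices of one breath (TIF50, TEF50, IE50)
#'
#' The 50% level of each limb is the limb's start displacement plus half its
#' excursion. The crossing time is located by linear interpolation between
#' the bracketing samples (first crossing if the limb is non-monotone) and
#' the displacement rate is linearly interpolated at that time. Rates are
#' returned as magnitudes; `ie50 = tif50 / tef50`.
#'
#' @inheritParams compute_rate_params
#' @param displacement total-channel displacement (gap-filled); defaults to
#'   the trace's total channel.
#' @return list with `tif50`, `tef50`, `ie50`; all `NA` (with a warning) if
#'   either limb has no 50% crossing.
#' @export
compute_loop_params <- function(breath, trace, rate, displacement = NULL) {
  x <- if (is.null(displacement))
    fill_gaps(trace$time, trace$channels$total)$x else displacement
  s <- breath$start_index; p <- breath$peak_index; e <- breath$end_index
  if (x[p] - x[s] <= 0 || x[p] - x[e] <= 0)
    stop("breath displacement range is not positive")
  lev_i <- x[s] + 0.5 * (x[p] - x[s])
  lev_e <- x[p] + 0.5 * (x[e] - x[p])
  t_i <- first_crossing_time(x, trace$time, s:p, lev_i)
  t_e <- first_crossing_time(x, trace$time, p:e, lev_e)
  if (is.na(t_i) || is.na(t_e)) {
    warning("no 50% crossing found within a limb")
    return(list(tif50 = NA_real_, tef50 = NA_real_, ie50 = NA_real_))
  }
  tif50 <- abs(interp_at(trace$time, rate, t_i))
  tef50 <- abs(interp_at(trace$time, rate, t_e))
  list(tif50 = tif50, tef50 = tef50, ie50 = tif50 / tef50)
}

#' Relative contribution of one region to another
#'
#' Peak-to-peak amplitude of the numerator channel over the breath's time
#' span, divided by the peak-to-peak amplitude of the denominator channel
#' over the same span, as a percentage.
#'
#' @param breath one detection-table row.
#' @param trace the trace.
#' @param numerator_region,denominator_region channel names (default thorax
#'   relative to total, the relative thoracic contribution rCT).
#' @return percentage (numeric scalar).
#' @export
compute_relative_contribution <- function(breath, trace,
                                          numerator_region = "thorax",
                                          denominator_region = "total") {
  for (ch in c(numerator_region, denominator_region))
    if (!ch %in% names(trace$channels)) stop("channel not present: ", ch)
  idx <- breath_span(breath)
  p2p <- function(ch) {
    v <- fill_gaps(trace$time, trace$channels[[ch]])$x[idx]
    max(v) - min(v)
  }
  num <- p2p(numerator_region)
  den <- p2p(denominator_region)
  if (den <= 1e-9 * max(num, 1e-300))
    stop("zero excursion in denominator region")
  100 * num / den
}

#' Konno-Mead phase between two compartments over one breath
#'
#' The loop plots the reference compartment on the vertical axis against the
#' second compartment on the horizontal axis over one respiratory cycle.
#' `m` is the horizontal width of the loop where the reference crosses 50% of
#' its excursion (crossings are paired in time order and their separations
#' averaged when the 50% line cuts the loop more than twice); `s` is the full
#' excursion of the second signal; the phase magnitude is
#' `asin(m/s)` in degrees. The sign is positive when the reference leads the
#' second compartment (negative enclosed loop area with these axes) and
#' negative when it lags; loops enclosing less than `1e-6` of the product of
#' the two excursions are reported as degenerate with phase 0.
#'
#' @param breath one detection-table row.
#' @param trace the trace.
#' @param reference,second channel names; defaults give thoracoabdominal
#'   asynchrony (thorax as reference against abdomen).
#' @return list with `m`, `s`, `rotation`
#'   (`"clockwise"`, `"counterclockwise"`, `"degenerate"`), `phase_deg`.
#' @export
compute_phase <- function(breath, trace, reference = "thorax",
                          second = "abdomen") {
  for (ch in c(reference, second))
    if (!ch %in% names(trace$channels)) stop("channel not present: ", ch)
  idx <- breath_span(breath)
  time <- trace$time
  yr <- fill_gaps(time, trace$channels[[reference]])$x
  ys <- fill_gaps(time, trace$channels[[second]])$x
  r <- yr[idx]; s2 <- ys[idx]
  exc_r <- max(r) - min(r)
  exc_s <- max(s2) - min(s2)
  if (exc_r <= 0 || exc_s <= 0) stop("zero excursion in a phase signal")

  level <- min(r) + 0.5 * exc_r
  v <- r - level
  cross <- which(v[-length(v)] * v[-1] < 0)
  widths <- numeric(0)
  if (length(cross) >= 2) {
    tc <- vapply(cross, function(j) {
      f <- (level - r[j]) / (r[j + 1] - r[j])
      time[idx[j]] + f * (time[idx[j + 1]] - time[idx[j]])
    }, numeric(1))
    sc <- interp_at(time[idx], s2, tc)
    np <- floor(length(sc) / 2)
    widths <- abs(sc[2 * seq_len(np)] - sc[2 * seq_len(np) - 1])
  }
  m <- if (length(widths)) mean(widths) else 0

  # signed loop area, second on x, reference on y, polygon closed in time
  xs <- s2; ysg <- r
  area <- 0.5 * sum(xs * c(ysg[-1], ysg[1]) - c(xs[-1], xs[1]) * ysg)
  degen <- abs(area) < 1e-6 * exc_r * exc_s
  rotation <- if (degen) "degenerate"
              else if (area < 0) "clockwise" else "counterclockwise"
  phase <- if (degen) 0 else
    -sign(area) * asin(min(m / exc_s, 1)) * 180 / pi
  list(m = m, s = exc_s, rotation = rotation, phase_deg = phase)
}

#' Assemble the full parameter record for one breath
#'
#' Computes all timing, displacement-rate, loop-shape and (when the regional
#' channels are present) regional parameters. Component failures become
#' missing values rather than aborting the recording.
#'
#' @param breath one detection-table row.
#' @param trace the trace.
#' @param rate total-channel displacement rate; computed when `NULL`.
#' @param displacement gap-filled total displacement; computed when `NULL`.
#' @param subject_id optional id carried into the record.
#' @return one-row data frame (a breath record).
#' @export
compute_breath_record <- function(breath, trace, rate = NULL,
                                  displacement = NULL, subject_id = NA) {
  if (is.null(rate)) rate <- compute_rate(trace)
  if (is.null(displacement))
    displacement <- fill_gaps(trace$time, trace$channels$total)$x
  row <- record_row(breath, trace, rate, displacement)
  cbind(data.frame(subject_id = subject_id, breath_id = breath$breath_id),
        as.data.frame(as.list(row)))
}

record_fields <- c("tI", "tE", "tTot", "rr", "tI_over_tE", "tI_over_tTot",
                   "ptif", "ptef", "tptif_over_tI", "tptef_over_tE",
                   "tif50", "tef50", "ie50", "rct", "taa_deg", "hta_deg")

# all parameters of one breath as a named numeric vector; component errors
# become NAs so one pathological breath never aborts the recording
record_row <- function(breath, trace, rate, displacement) {
  out <- stats::setNames(rep(NA_real_, length(record_fields)), record_fields)
  tm <- tryCatch(compute_timing(breath, trace), error = function(e) NULL)
  if (!is.null(tm)) out[names(tm)] <- unlist(tm)
  rp <- tryCatch(compute_rate_params(breath, trace, rate),
                 error = function(e) NULL)
  if (!is.null(rp)) out[names(rp)] <- unlist(rp)
  lp <- tryCatch(suppressWarnings(
    compute_loop_params(breath, trace, rate, displacement)),
    error = function(e) NULL)
  if (!is.null(lp)) out[names(lp)] <- unlist(lp)
  has <- function(...) all(c(...) %in% names(trace$channels))
  if (has("thorax", "total"))
    out["rct"] <- tryCatch(compute_relative_contribution(breath, trace),
                           error = function(e) NA_real_)
  if (has("thorax", "abdomen"))
    out["taa_deg"] <- tryCatch(
      compute_phase(breath, trace, "thorax", "abdomen")$phase_deg,
      error = function(e) NA_real_)
  if (has("thorax_left", "thorax_right"))
    out["hta_deg"] <- tryCatch(
      compute_phase(breath, trace, "thorax_left", "thorax_right")$phase_deg,
      error = function(e) NA_real_)
  out
}

#' Per-breath parameter table for all valid breaths of a trace
#'
#' @param trace the trace.
#' @param breaths filtered detection table; recomputed when `NULL`.
#' @param subject_id optional id column value.
#' @return data frame with one row per valid breath.
#' @export
breath_table <- function(trace, breaths = NULL, subject_id = NA) {
  if (is.null(breaths)) {
    breaths <- filter_breaths(detect_breaths(trace), detect_artifacts(trace))
  }
  valid <- breaths[breaths$valid, , drop = FALSE]
  # gap-fill every channel once; the per-breath helpers then see NA-free
  # signals and skip re-interpolation
  trace$channels <- lapply(trace$channels,
                           function(ch) fill_gaps(trace$time, ch)$x)
  rate <- compute_rate(trace)
  displacement <- trace$channels$total
  mat <- matrix(NA_real_, nrow(valid), length(record_fields),
                dimnames = list(NULL, record_fields))
  for (i in seq_len(nrow(valid))) {
    b <- list(breath_id = valid$breath_id[i],
              start_index = valid$start_index[i],
              peak_index = valid$peak_index[i],
              end_index = valid$end_index[i],
              start_time = valid$start_time[i],
              peak_time = valid$peak_time[i],
              end_time = valid$end_time[i])
    mat[i, ] <- record_row(b, trace, rate, displacement)
  }
  cbind(data.frame(subject_id = rep(subject_id, nrow(valid)),
                   breath_id = valid$breath_id),
        as.data.frame(mat))
}
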