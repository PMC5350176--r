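#' Multi-region displacement trace
#'
#' Container for a thoracoabdominal displacement recording on a uniform time
#' grid. The `total` channel is required; regional channels (`thorax`,
#' `abdomen`, `thorax_left`, `thorax_right`, `abdomen_left`, `abdomen_right`)
#' are optional. Missing samples (dropouts) are stored as `NA`.
#'
#' @param time sample times in seconds, uniform grid (checked to 1 ppm).
#' @param channels named list of numeric vectors, each the same length as
#'   `time`; must contain `total`.
#' @param sampling_rate samples per second; inferred from `time` when `NULL`.
#' @return an object of class `displacement_trace`.
#' @export
displacement_trace <- function(time, channels, sampling_rate = NULL) {
  stopifnot(is.numeric(time), length(time) >= 2)
  if (!("total" %in% names(channels)))
    stop("total channel is required")
  len <- vapply(channels, length, integer(1))
  if (any(len != length(time)))
    stop("all channels must have the same length as time")
  dt <- diff(time)
  dt0 <- stats::median(dt)
  if (any(abs(dt - dt0) > 1e-6 * dt0))
    stop("time grid is not uniform (beyond 1 ppm tolerance)")
  fs <- if (is.null(sampling_rate)) 1 / dt0 else sampling_rate
  if (length(time) < 2 * fs)
    stop("trace too short: length >= 2 s required")
  structure(list(time = as.numeric(time),
                 channels = lapply(channels, as.numeric),
                 sampling_rate = fs),
            class = "displacement_trace")
}

#' @export
print.displacement_trace <- function(x, ...) {
  dur <- x$time[length(x$time)] - x$time[1]
  cat(sprintf("<displacement_trace> %.1f s at %.4g Hz, channels: %s\n",
              dur, x$sampling_rate, paste(names(x$channels), collapse = ", ")))
  na <- sum(is.na(x$channels$total))
  if (na > 0) cat(sprintf("  %d missing samples in total channel\n", na))
  invisible(x)
}

#' @export
plot.displacement_trace <- function(x, channels = names(x$channels), ...) {
  graphics::matplot(x$time,
                    do.call(cbind, x$channels[channels]),
                    type = "l", lty = 1,
                    xlab = "time (s)", ylab = "displacement (a.u.)", ...)
  graphics::legend("topright", legend = channels, lty = 1,
                   col = seq_along(channels), bty = "n", cex = 0.8)
  invisible(x)
}

trace_channel_order <- c("total", "thorax", "abdomen",
                         "thorax_left", "thorax_right",
                         "abdomen_left", "abdomen_right")

#' Write a displacement trace to a comma-separated file
#'
#' Column layout is `time_s` followed by whichever of the standard region
#' columns are present. Missing samples are written as empty fields.
#'
#' @param trace a [displacement_trace()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  chans <- intersect(trace_channel_order, names(trace$channels))
  df <- data.frame(time_s = trace$time, trace$channels[chans],
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, na = "", quote = FALSE)
  invisible(path)
}

#' Read a displacement trace written by [write_trace()]
#'
#' Columns are matched by header name, not position. Empty fields become
#' missing samples.
#'
#' @param path input file path.
#' @param sampling_rate optional override; inferred from the time column when
#'   `NULL`.
#' @return a [displacement_trace()].
#' @export
read_trace <- function(path, sampling_rate = NULL) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!("time_s" %in% names(df))) stop("missing time_s column")
  if (!("total" %in% names(df))) stop("missing total column")
  chans <- intersect(trace_channel_order, names(df))
  displacement_trace(df$time_s, as.list(df[chans]), sampling_rate)
}
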