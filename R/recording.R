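#' Construct a triaxial accelerometer recording
#'
#' The basic container for a pen recording: three acceleration channels in
#' units of g on a uniform time base. The constructor validates uniform
#' sampling against the nominal rate.
#'
#' @param ax,ay,az Numeric vectors, acceleration in g, one value per sample.
#' @param fs Sampling rate in Hz.
#' @param t Optional vector of sample times in seconds. When `NULL`
#'   (the default) the time base is `(0:(n-1))/fs`.
#' @param meta Named list of free-form provenance strings (device, subject
#'   label, scale setting, ...).
#' @param dt_tol Maximum tolerated absolute deviation of successive time
#'   differences from `1/fs`, in seconds.
#'
#' @return An object of class `accel_recording`: a list with elements
#'   `t`, `ax`, `ay`, `az`, `fs`, `meta`.
#' @seealso [read_pen_recording()], [magnitude()]
#' @export
#' @examples
#' rec <- accel_recording(ax = c(1, 1, 1), ay = c(0, 0, 0), az = c(0, 0, 0),
#'                        fs = 100)
#' rec
accel_recording <- function(ax, ay, az, fs, t = NULL, meta = list(),
                            dt_tol = 1e-4) {
  n <- length(ax)
  if (n < 2L || length(ay) != n || length(az) != n)
    stop_data("accelerometer channels must have equal length >= 2 (got %d, %d, %d)",
              n, length(ay), length(az))
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop_param("'fs' must be a single positive number")
  if (is.null(t)) t <- (seq_len(n) - 1) / fs
  if (length(t) != n)
    stop_data("time vector length (%d) does not match channel length (%d)",
              length(t), n)
  dts <- diff(t)
  bad <- which(dts <= 0)
  if (length(bad))
    stop_data("sample times not strictly increasing; first offending row: %d",
              bad[1L] + 1L)
  dev <- max(abs(dts - 1 / fs))
  if (dev > dt_tol)
    stop_data("sampling not uniform at fs = %g Hz: max |dt - 1/fs| = %.3g s exceeds tolerance %.3g s",
              fs, dev, dt_tol)
  structure(list(t = as.numeric(t), ax = as.numeric(ax), ay = as.numeric(ay),
                 az = as.numeric(az), fs = fs, meta = meta),
            class = "accel_recording")
}

#' @export
print.accel_recording <- function(x, ...) {
  cat(sprintf("<accel_recording> %d samples @ %g Hz, duration %.2f s\n",
              length(x$t), x$fs, x$t[length(x$t)] - x$t[1L]))
  if (length(x$meta))
    cat("  meta:", paste(names(x$meta), unlist(x$meta), sep = "=",
                         collapse = ", "), "\n")
  invisible(x)
}

#' Accelerometer count-to-g scaling configuration
#'
#' Raw sensor output is in integer counts; conversion to g is affine:
#' `g = (counts - offset) / counts_per_g`. The default matches an LSM6DSL
#' configured at its +/-2 g full-scale range (16384 counts per g, zero
#' offset); the configured range of a given pen is not always known, so both
#' values are overridable.
#'
#' @param counts_per_g Sensitivity in counts per g; must be positive.
#' @param offset Zero-g offset in counts (per-axis scalar).
#' @param full_scale Full-scale range in g (informational).
#' @return Object of class `scale_config`.
#' @export
scale_config <- function(counts_per_g = 16384, offset = 0, full_scale = 2) {
  if (!is.numeric(counts_per_g) || counts_per_g <= 0)
    stop_param("'counts_per_g' must be positive")
  structure(list(counts_per_g = counts_per_g, offset = offset,
                 full_scale = full_scale),
            class = "scale_config")
}

counts_to_g <- function(counts, scale) (counts - scale$offset) / scale$counts_per_g
g_to_counts <- function(g, scale) round(g * scale$counts_per_g + scale$offset)

#' Read a pen accelerometer recording from delimited text
#'
#' Reads a delimited text export of raw accelerometer counts (one header
#' line) and rescales it to g. A time column is optional; when absent the
#' time base is reconstructed as `index/fs`. When present, times are rebased
#' so the first sample sits at t = 0 (each file carries its own clock;
#' cross-device alignment happens later, in [match_events()]).
#'
#' @param path Path to the delimited text file.
#' @param scale A [scale_config()] describing the count-to-g conversion.
#' @param fs Sampling rate in Hz, used when the file has no time column and
#'   to validate uniform sampling.
#' @param sep Field separator (default comma).
#' @param time_col,axis_cols Column names for time (optional in the file)
#'   and the three axes.
#' @param meta Passed through to [accel_recording()].
#' @return An [accel_recording()] in g units.
#' @export
read_pen_recording <- function(path, scale = scale_config(), fs = 100,
                               sep = ",", time_col = "t",
                               axis_cols = c("ax", "ay", "az"),
                               meta = list()) {
  if (!file.exists(path)) stop_data("recording file not found: %s", path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  for (col in axis_cols)
    if (!col %in% names(df))
      stop_format("missing required column '%s' in %s", col, path)
  t <- NULL
  if (time_col %in% names(df)) {
    t <- df[[time_col]]
    t <- t - t[1L]
  }
  meta$path <- path
  accel_recording(ax = counts_to_g(df[[axis_cols[1L]]], scale),
                  ay = counts_to_g(df[[axis_cols[2L]]], scale),
                  az = counts_to_g(df[[axis_cols[3L]]], scale),
                  fs = fs, t = t, meta = meta)
}

#' Write a recording as a raw-count delimited text file
#'
#' Inverse of [read_pen_recording()]: converts g back to integer counts via
#' the same affine scale and writes a header + data rows. Values quantized to
#' the count grid round-trip exactly.
#'
#' @inheritParams read_pen_recording
#' @param rec An [accel_recording()].
#' @param write_time Include the time column?
#' @return Invisibly, `path`.
#' @export
write_pen_recording <- function(rec, path, scale = scale_config(), sep = ",",
                                write_time = TRUE) {
  df <- data.frame(ax = g_to_counts(rec$ax, scale),
                   ay = g_to_counts(rec$ay, scale),
                   az = g_to_counts(rec$az, scale))
  if (write_time) df <- cbind(t = rec$t, df)
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Construct a beat-event series
#'
#' A sequence of beat timestamps (the "t-vector"): detected accelerometer
#' peaks, ECG R-wave times, or simulation ground truth.
#'
#' @param times Numeric vector of beat times in seconds; strictly
#'   increasing, all non-negative.
#' @param source Label: `"pen"`, `"ecg"` or `"truth"` (free-form allowed).
#' @return Object of class `event_series` with elements `times`, `source`.
#' @export
event_series <- function(times, source = "pen") {
  times <- as.numeric(times)
  if (length(times) && any(times < 0))
    stop_data("event times must be non-negative")
  if (length(times) > 1L && any(diff(times) <= 0))
    stop_data("event times must be strictly increasing; first offending index: %d",
              which(diff(times) <= 0)[1L] + 1L)
  structure(list(times = times, source = source), class = "event_series")
}

#' @export
print.event_series <- function(x, ...) {
  cat(sprintf("<event_series> %d events [%s]", length(x$times), x$source))
  if (length(x$times))
    cat(sprintf(", span %.2f-%.2f s", x$times[1L], x$times[length(x$times)]))
  cat("\n")
  invisible(x)
}

#' Read a beat-event log
#'
#' Reads a one-column delimited text log of reference beats. Two dialects
#' exist in the wild: absolute beat timestamps, or successive RR intervals
#' (as exported by ECG evaluation kits). RR intervals are converted to
#' timestamps by cumulative summation from `origin`.
#'
#' @param path Path to the log file (one header line, one value per row).
#' @param dialect `"timestamps"` or `"rr"`.
#' @param origin Time of the reference point preceding the first RR interval
#'   (seconds); used only for the `"rr"` dialect.
#' @param source Label stored on the returned series.
#' @param sep Field separator.
#' @return An [event_series()] in seconds.
#' @export
read_event_log <- function(path, dialect = c("timestamps", "rr"), origin = 0,
                           source = "ecg", sep = ",") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop_data("event log not found: %s", path)
  df <- utils::read.table(path, header = TRUE, sep = sep)
  if (nrow(df) == 0L) stop_data("event log is empty: %s", path)
  v <- as.numeric(df[[1L]])
  if (anyNA(v)) stop_format("non-numeric values in event log %s", path)
  if (dialect == "rr") {
    if (any(v <= 0))
      stop_data("non-positive RR interval at row %d in %s",
                which(v <= 0)[1L], path)
    v <- origin + cumsum(v)
  }
  event_series(v, source = source)
}

#' Write a beat-event series as a one-column log
#'
#' @param events An [event_series()].
#' @param path Output path.
#' @param sep Field separator.
#' @return Invisibly, `path`.
#' @export
write_event_log <- function(events, path, sep = ",") {
  utils::write.table(data.frame(time_s = events$times), path, sep = sep,
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
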