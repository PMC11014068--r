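#' Ordinary least squares of pen timestamps on reference timestamps
#'
#' Fits `pen = slope * ecg + intercept` over matched beat timestamps.
#' Perfect agreement gives the identity line (slope 1, intercept 0); the
#' fitted line quantifies residual clock drift and offset.
#'
#' @param matched_pen,matched_ecg Numeric vectors of equal length >= 2; the
#'   reference (`matched_ecg`) must have nonzero variance.
#' @return List with `slope` and `intercept`.
#' @export
timestamp_regression <- function(matched_pen, matched_ecg) {
  if (length(matched_pen) != length(matched_ecg) || length(matched_pen) < 2L)
    stop_param("matched timestamp vectors must have equal length >= 2")
  if (stats::var(matched_ecg) == 0)
    stop_data("reference timestamps have zero variance")
  fit <- stats::lm(matched_pen ~ matched_ecg)
  cf <- stats::coef(fit)
  list(slope = unname(cf[2L]), intercept = unname(cf[1L]))
}

#' Scan low-pass cutoff frequencies against a reference beat series
#'
#' The cutoff-verification loop: for each candidate cutoff, design the
#' low-pass, filter the (detrended) magnitude trace, detect peaks, and score
#' the cutoff by how close the detected beat count comes to the reference
#' count, `objective = |count - n_reference|`. Ties are broken by the higher
#' Pearson correlation of matched pen-vs-reference timestamps, and any
#' remaining tie by the lower cutoff (stronger noise rejection). This is a
#' development/validation tool: it requires a reference (ECG or
#' ground-truth) beat series.
#'
#' @param trace A [magnitude_trace()] (raw magnitude or detrended), *not*
#'   yet filtered.
#' @param reference An [event_series()] of reference beats.
#' @param grid Candidate cutoff frequencies in Hz; all must lie in
#'   (0, fs/2). Default 0.5-8 Hz in 0.25 Hz steps.
#' @param params [peak_params()] used at every cutoff.
#' @param order Butterworth order.
#' @param zero_phase Zero-phase application (recommended; see
#'   [butter_lowpass()]).
#' @param max_offset Matching window for the tie-break correlation and the
#'   reported regression, seconds.
#' @return Object of class `cutoff_scan`: `grid`, `peak_counts`,
#'   `objective`, `selected_cutoff`, `regression` (timestamp OLS at the
#'   selected cutoff), `n_reference`.
#' @export
scan_cutoffs <- function(trace, reference, grid = seq(0.5, 8, by = 0.25),
                         params = peak_params(), order = 4, zero_phase = TRUE,
                         max_offset = 1) {
  stopifnot(inherits(trace, "magnitude_trace"),
            inherits(reference, "event_series"))
  if (!length(grid)) stop_param("cutoff grid is empty")
  if (any(grid <= 0 | grid >= trace$fs / 2))
    stop_param("all grid cutoffs must lie in (0, fs/2) = (0, %g)", trace$fs / 2)
  grid <- sort(grid)
  n_ref <- length(reference$times)
  events <- vector("list", length(grid))
  counts <- integer(length(grid))
  for (k in seq_along(grid)) {
    spec <- butter_lowpass(order, grid[k], trace$fs, zero_phase = zero_phase)
    ev <- detect_peaks(apply_filter(trace, spec), params, warn_empty = FALSE)
    events[[k]] <- ev
    counts[k] <- length(ev$times)
  }
  objective <- abs(counts - n_ref)
  tied <- which(objective == min(objective))
  sel <- tied[1L]
  if (length(tied) > 1L) {
    # tie-break: higher matched-timestamp Pearson correlation, then lower cutoff
    rs <- vapply(tied, function(k) {
      ev <- events[[k]]
      if (length(ev$times) < 2L) return(-Inf)
      mr <- match_events(ev, reference, max_offset = max_offset)
      if (nrow(mr$pairs) < 2L) return(-Inf)
      pearson_r(ev$times[mr$pairs[, 1L]], reference$times[mr$pairs[, 2L]])
    }, numeric(1L))
    sel <- tied[which.max(rs)]  # which.max takes the first (= lowest cutoff) tie
  }
  reg <- list(slope = NA_real_, intercept = NA_real_)
  ev <- events[[sel]]
  if (length(ev$times) >= 2L) {
    mr <- match_events(ev, reference, max_offset = max_offset)
    if (nrow(mr$pairs) >= 2L)
      reg <- timestamp_regression(ev$times[mr$pairs[, 1L]],
                                  reference$times[mr$pairs[, 2L]])
  }
  structure(list(grid = grid, peak_counts = counts, objective = objective,
                 selected_cutoff = grid[sel], regression = reg,
                 n_reference = n_ref),
            class = "cutoff_scan")
}

#' @export
print.cutoff_scan <- function(x, ...) {
  cat(sprintf("<cutoff_scan> %d cutoffs, reference beats: %d\n",
              length(x$grid), x$n_reference))
  cat(sprintf("  selected cutoff: %g Hz (peak count %d)\n", x$selected_cutoff,
              x$peak_counts[x$grid == x$selected_cutoff][1L]))
  if (!is.na(x$regression$slope))
    cat(sprintf("  timestamp regression at selection: pen = %.4f * ref %+.4f\n",
                x$regression$slope, x$regression$intercept))
  invisible(x)
}

#' @export
plot.cutoff_scan <- function(x, ...) {
  plot(x$grid, x$peak_counts, type = "b", xlab = "cutoff (Hz)",
       ylab = "detected peaks", main = "cutoff scan", ...)
  graphics::abline(h = x$n_reference, lty = 2)
  graphics::abline(v = x$selected_cutoff, col = "red")
  invisible(x)
}

#' Pooled cutoff selection over several recordings
#'
#' Combines per-recording scans (all on the same grid) and selects the
#' cutoff minimizing the summed objective, ties broken by the lower cutoff.
#' Reports both the pooled choice and the per-recording selections, so
#' per-subject and global calibration can be compared.
#'
#' @param scans List of [scan_cutoffs()] results sharing a grid.
#' @return List with `selected_cutoff` (pooled), `per_recording` (vector of
#'   per-scan selections) and `total_objective` (per grid point).
#' @export
select_cutoff_pooled <- function(scans) {
  if (!length(scans)) stop_param("need at least one scan")
  grid <- scans[[1L]]$grid
  for (s in scans)
    if (!identical(s$grid, grid))
      stop_param("all scans must share the same cutoff grid")
  tot <- Reduce(`+`, lapply(scans, `[[`, "objective"))
  list(selected_cutoff = grid[which.min(tot)],
       per_recording = vapply(scans, `[[`, numeric(1L), "selected_cutoff"),
       total_objective = tot)
}
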