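#' Beat-peak detector parameters
#'
#' The detector keeps strict local maxima of the filtered trace that (1)
#' rise at least `height_frac` standard deviations above the trace mean,
#' (2) have topographic prominence of at least `prominence_frac` standard
#' deviations, and (3) are separated by at least `min_rr` seconds (enforced
#' greedily, tallest peak first). Thresholds are expressed relative to the
#' trace's own standard deviation so they adapt to signal amplitude.
#'
#' @param min_rr Minimum separation between accepted peaks, seconds. The
#'   default 0.33 s corresponds to a ~181 bpm ceiling, above any resting
#'   writing scenario.
#' @param prominence_frac Prominence threshold as a fraction of `sd(trace)`.
#' @param height_frac Height threshold: peaks must exceed
#'   `mean(trace) + height_frac * sd(trace)`. On a detrended trace this
#'   rejects low-lying noise maxima in the valleys between beats that can
#'   still carry non-trivial prominence.
#' @param interpolate Refine each peak time by parabolic (3-point)
#'   interpolation around the maximal sample? Default `FALSE`: peak time is
#'   the time of the maximal sample.
#' @return Object of class `peak_params`.
#' @export
peak_params <- function(min_rr = 0.33, prominence_frac = 0.5,
                        height_frac = 0.75, interpolate = FALSE) {
  if (min_rr <= 0) stop_param("'min_rr' must be positive")
  if (prominence_frac < 0) stop_param("'prominence_frac' must be >= 0")
  if (height_frac < 0) stop_param("'height_frac' must be >= 0")
  structure(list(min_rr = min_rr, prominence_frac = prominence_frac,
                 height_frac = height_frac, interpolate = interpolate),
            class = "peak_params")
}

# Topographic prominence of candidate indices: walk from each peak to the
# nearest strictly higher sample (or the trace edge) on each side, take the
# minimum over each stretch, and subtract the higher of the two minima.
peak_prominences <- function(a, idx) {
  n <- length(a)
  vapply(idx, function(i) {
    h <- a[i]
    j <- i - 1L; lmin <- h
    while (j >= 1L && a[j] <= h) { if (a[j] < lmin) lmin <- a[j]; j <- j - 1L }
    j <- i + 1L; rmin <- h
    while (j <= n && a[j] <= h) { if (a[j] < rmin) rmin <- a[j]; j <- j + 1L }
    h - max(lmin, rmin)
  }, numeric(1L))
}

#' Detect beat peaks on a filtered magnitude trace
#'
#' @param trace A [magnitude_trace()], normally with `stage = "filtered"`.
#' @param params A [peak_params()] object.
#' @param warn_empty Emit a diagnostic warning when no peak is found on a
#'   trace of physiological length (>= 60 s)? A writing recording with no
#'   detectable beats usually indicates a scaling or filtering problem.
#' @return An [event_series()] of peak times (`source = "pen"`), with the
#'   integer sample indices attached as attribute `"index"`.
#' @export
#' @examples
#' t <- seq(0, 10, by = 0.01)
#' tr <- magnitude_trace(t, sin(2 * pi * t), fs = 100, stage = "filtered")
#' length(detect_peaks(tr)$times)   # 10 cycles -> 10 peaks
detect_peaks <- function(trace, params = peak_params(), warn_empty = TRUE) {
  stopifnot(inherits(trace, "magnitude_trace"))
  a <- trace$a
  n <- length(a)
  keep <- integer(0L)
  if (n >= 3L) {
    cand <- which(a[2:(n - 1L)] > a[1:(n - 2L)] & a[2:(n - 1L)] > a[3:n]) + 1L
    if (length(cand)) {
      s <- stats::sd(a)
      hmin <- mean(a) + params$height_frac * s
      pmin <- params$prominence_frac * s
      cand <- cand[a[cand] >= hmin]
      if (length(cand)) cand <- cand[peak_prominences(a, cand) >= pmin]
      # enforce min_rr greedily, tallest first (earlier index wins ties)
      if (length(cand)) {
        ord <- cand[order(-a[cand], cand)]
        for (i in ord) {
          if (!length(keep) ||
              all(abs(trace$t[i] - trace$t[keep]) >= params$min_rr))
            keep <- c(keep, i)
        }
        keep <- sort(keep)
      }
    }
  }
  times <- trace$t[keep]
  if (params$interpolate && length(keep)) {
    inner <- keep > 1L & keep < n
    i <- keep[inner]
    denom <- a[i - 1L] - 2 * a[i] + a[i + 1L]
    delta <- ifelse(denom < 0, 0.5 * (a[i - 1L] - a[i + 1L]) / denom, 0)
    times[inner] <- trace$t[i] + pmax(pmin(delta, 0.5), -0.5) / trace$fs
  }
  dur <- if (n) trace$t[n] - trace$t[1L] else 0
  if (warn_empty && !length(keep) && dur >= 60)
    warning(sprintf("no beat peaks detected on a %.0f s trace; check scaling and filter settings", dur),
            call. = FALSE)
  ev <- event_series(times, source = "pen")
  attr(ev, "index") <- keep
  ev
}

#' Successive inter-beat intervals (the delta-t vector)
#'
#' @param events An [event_series()] with at least two events.
#' @return Object of class `interval_series`: list with `dt` (seconds,
#'   length one less than the number of events) and `source`.
#' @export
beat_intervals <- function(events) {
  stopifnot(inherits(events, "event_series"))
  if (length(events$times) < 2L)
    stop_data("need at least 2 events to form intervals (got %d)",
              length(events$times))
  structure(list(dt = diff(events$times), source = events$source),
            class = "interval_series")
}

#' @export
print.interval_series <- function(x, ...) {
  cat(sprintf("<interval_series> %d intervals [%s], mean %.3f s\n",
              length(x$dt), x$source, mean(x$dt)))
  invisible(x)
}

#' Instantaneous heart rate from an RR interval
#'
#' `HR = 60 / dt` converts an inter-beat interval in seconds to beats per
#' minute. Vectorized.
#'
#' @param dt RR interval(s) in seconds; all must be positive.
#' @return Heart rate(s) in bpm.
#' @export
#' @examples
#' heart_rate(1.0)    # 60
#' heart_rate(0.5)    # 120
heart_rate <- function(dt) {
  if (any(dt <= 0)) stop_param("RR intervals must be positive")
  60 / dt
}

#' Summary statistics of an interval series
#'
#' Mean interval, its sample standard deviation (an SDNN-like heart rate
#' variability index), the mean heart rate and the beat count. The mean
#' heart rate is defined as `60 / mean(dt)` -- the rate whose period equals
#' the mean interval -- rather than the mean of per-beat rates.
#'
#' @param x An [interval_series()] (or a bare numeric vector of intervals).
#' @param source Label override when `x` is a bare vector.
#' @return Object of class `hr_summary` with `mean_dt`, `sd_dt`, `mean_hr`,
#'   `n_beats`, `source`.
#' @export
hr_summary <- function(x, source = NULL) {
  if (inherits(x, "interval_series")) {
    dt <- x$dt
    if (is.null(source)) source <- x$source
  } else {
    dt <- as.numeric(x)
    if (is.null(source)) source <- "unknown"
  }
  if (!length(dt)) stop_data("empty interval series")
  if (any(dt <= 0)) stop_data("intervals must be positive")
  structure(list(mean_dt = mean(dt),
                 sd_dt = if (length(dt) > 1L) stats::sd(dt) else 0,
                 mean_hr = 60 / mean(dt),
                 n_beats = length(dt) + 1L,
                 source = source),
            class = "hr_summary")
}

#' @export
print.hr_summary <- function(x, ...) {
  cat(sprintf("<hr_summary> [%s] mean dt %.3f s (sd %.3f), mean HR %.2f bpm, %d beats\n",
              x$source, x$mean_dt, x$sd_dt, x$mean_hr, x$n_beats))
  invisible(x)
}

#' Samples per cardiac period
#'
#' At sampling rate `fs`, a mean inter-beat interval of `mean_dt` seconds
#' spans `fs * mean_dt` samples -- e.g. 71.4 samples at 100 Hz for a 0.714 s
#' interval. Useful for judging how well a beat is resolved at a given rate.
#'
#' @param fs Sampling rate in Hz.
#' @param mean_dt Mean RR interval in seconds.
#' @return Samples per period (may be fractional).
#' @export
samples_per_period <- function(fs, mean_dt) {
  if (fs <= 0 || any(mean_dt <= 0)) stop_param("'fs' and 'mean_dt' must be positive")
  fs * mean_dt
}
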