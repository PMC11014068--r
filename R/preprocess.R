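#' Construct a single-channel magnitude trace
#'
#' Internal-facing constructor; users normally obtain traces via
#' [magnitude()] and transform them with [detrend_trace()] and
#' [apply_filter()].
#'
#' @param t Sample times in seconds, strictly increasing.
#' @param a Signal values in g.
#' @param fs Sampling rate in Hz.
#' @param stage Processing stage label: `"raw_magnitude"`, `"detrended"` or
#'   `"filtered"`.
#' @return Object of class `magnitude_trace`.
#' @export
magnitude_trace <- function(t, a, fs,
                            stage = c("raw_magnitude", "detrended", "filtered")) {
  stage <- match.arg(stage)
  if (length(t) != length(a))
    stop_data("time and signal vectors differ in length (%d vs %d)",
              length(t), length(a))
  if (length(t) > 1L && any(diff(t) <= 0))
    stop_data("trace times must be strictly increasing")
  if (stage == "raw_magnitude" && any(a < 0))
    stop_data("raw magnitude cannot be negative")
  structure(list(t = as.numeric(t), a = as.numeric(a), fs = fs, stage = stage),
            class = "magnitude_trace")
}

#' @export
print.magnitude_trace <- function(x, ...) {
  cat(sprintf("<magnitude_trace> %d samples @ %g Hz, stage=%s\n",
              length(x$t), x$fs, x$stage))
  invisible(x)
}

#' @export
plot.magnitude_trace <- function(x, ...) {
  plot(x$t, x$a, type = "l", xlab = "time (s)", ylab = "acceleration (g)",
       main = sprintf("magnitude trace (%s)", x$stage), ...)
  invisible(x)
}

#' Euclidean magnitude of a triaxial recording
#'
#' Fuses the three accelerometer axes into a single orientation-independent
#' channel, `a = sqrt(ax^2 + ay^2 + az^2)`. During quiet writing the
#' magnitude sits near 1 g (gravity) with the cardiac pulse riding on top,
#' regardless of how the pen is held.
#'
#' @param rec An [accel_recording()].
#' @return A [magnitude_trace()] with `stage = "raw_magnitude"`.
#' @export
#' @examples
#' rec <- accel_recording(ax = c(3, 0), ay = c(4, 0), az = c(0, 0), fs = 100)
#' magnitude(rec)$a   # 5, 0
magnitude <- function(rec) {
  stopifnot(inherits(rec, "accel_recording"))
  magnitude_trace(rec$t, sqrt(rec$ax^2 + rec$ay^2 + rec$az^2), rec$fs,
                  stage = "raw_magnitude")
}

#' Remove the quasi-static gravity offset from a magnitude trace
#'
#' The magnitude of a held pen is dominated by a ~1 g gravity offset; peak
#' prominence and amplitude thresholds are only meaningful once it is
#' removed. Three estimators of the offset are offered: the global mean
#' (default), the global median (robust to large strokes), and a centered
#' moving mean (tracks slow grip drift).
#'
#' @param trace A [magnitude_trace()] with `stage = "raw_magnitude"`.
#' @param method `"mean"`, `"median"` or `"moving_mean"`.
#' @param window Window length in seconds for `method = "moving_mean"`; must
#'   not exceed the trace duration.
#' @return A [magnitude_trace()] with `stage = "detrended"`; same length and
#'   time base.
#' @export
detrend_trace <- function(trace, method = c("mean", "median", "moving_mean"),
                          window = NULL) {
  stopifnot(inherits(trace, "magnitude_trace"))
  method <- match.arg(method)
  a <- trace$a
  baseline <- switch(method,
    mean = mean(a),
    median = stats::median(a),
    moving_mean = {
      if (is.null(window)) stop_param("'window' (seconds) required for moving_mean")
      dur <- trace$t[length(trace$t)] - trace$t[1L]
      if (window > dur + 1 / trace$fs)
        stop_param("moving-mean window (%g s) longer than trace (%g s)", window, dur)
      k <- max(1L, round(window * trace$fs) + 1L)
      running_mean(a, k)
    })
  magnitude_trace(trace$t, a - baseline, trace$fs, stage = "detrended")
}

# Centered running mean with partial windows at the edges; k in samples.
# A window covering the whole trace reduces to the global mean.
running_mean <- function(a, k) {
  n <- length(a)
  if (k >= n) return(rep(mean(a), n))
  half <- k %/% 2L
  cs <- cumsum(c(0, a))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}
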