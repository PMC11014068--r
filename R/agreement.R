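#' Align two beat-event series by monotone matching
#'
#' Pairs pen-detected beats with reference (ECG) beats. The pairing is the
#' monotone one-to-one matching that maximizes the number of pairs subject
#' to every pair lying within `max_offset` seconds of each other, breaking
#' ties by minimal total absolute offset (dynamic program over both series).
#' Two devices with independent clocks may also disagree by a constant
#' shift; with `estimate_shift = TRUE` a single global clock shift is chosen
#' first by maximizing the achievable pair count over a shift grid, and is
#' reported in the result.
#'
#' @param pen,ecg [event_series()] objects; both non-empty.
#' @param max_offset Maximum |pen time - (ecg time + shift)| for a pair,
#'   seconds. Default 1 s (observed pen/ECG peak delays stay below one
#'   second in practice).
#' @param estimate_shift Estimate a global clock shift first? Use `TRUE` for
#'   recordings made on independently clocked devices, `FALSE` (default)
#'   when both series share a time base (e.g. synthetic data).
#' @param max_shift Half-width of the shift search grid, seconds.
#' @param shift_step Shift grid step, seconds.
#' @return Object of class `match_result`: `pairs` (two-column matrix of pen
#'   and ecg indices, strictly increasing in both columns), `offsets`
#'   (`pen - (ecg + shift)` per pair), `n_unmatched_pen`, `n_unmatched_ecg`,
#'   `global_shift`.
#' @export
match_events <- function(pen, ecg, max_offset = 1, estimate_shift = FALSE,
                         max_shift = 5, shift_step = 0.05) {
  stopifnot(inherits(pen, "event_series"), inherits(ecg, "event_series"))
  if (!length(pen$times) || !length(ecg$times))
    stop_data("both event series must be non-empty")
  if (max_offset <= 0) stop_param("'max_offset' must be positive")
  p <- pen$times
  e <- ecg$times
  shift <- 0
  if (estimate_shift) {
    grid <- seq(-max_shift, max_shift, by = shift_step)
    scores <- vapply(grid, function(s) greedy_match(p, e + s, max_offset),
                     numeric(2L))
    best <- which(scores[1L, ] == max(scores[1L, ]))
    best <- best[scores[2L, best] == min(scores[2L, best])]
    shift <- grid[best][which.min(abs(grid[best]))]
  }
  m <- monotone_match(p, e + shift, max_offset)
  if (!nrow(m$pairs))
    warning("no pen/ECG beat pairs found within max_offset; check alignment",
            call. = FALSE)
  structure(list(pairs = m$pairs,
                 offsets = if (nrow(m$pairs))
                   p[m$pairs[, 1L]] - (e[m$pairs[, 2L]] + shift) else numeric(0L),
                 n_unmatched_pen = length(p) - nrow(m$pairs),
                 n_unmatched_ecg = length(e) - nrow(m$pairs),
                 global_shift = shift,
                 total_offset = m$cost),
            class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("<match_result> %d pairs (unmatched: %d pen, %d ecg), shift %.3f s\n",
              nrow(x$pairs), x$n_unmatched_pen, x$n_unmatched_ecg,
              x$global_shift))
  if (nrow(x$pairs))
    cat(sprintf("  mean |offset| %.3f s, max |offset| %.3f s\n",
                mean(abs(x$offsets)), max(abs(x$offsets))))
  invisible(x)
}

# Fast scoring for the shift search: greedy earliest-available assignment
# (optimal cardinality for this interval structure) plus its total |offset|
# as a cheap tie-breaking cost.
greedy_match <- function(p, e, max_offset) {
  n <- length(p); m <- length(e)
  cnt <- 0L; cost <- 0; j <- 1L
  for (i in seq_len(n)) {
    while (j <= m && e[j] < p[i] - max_offset) j <- j + 1L
    if (j > m) break
    if (abs(e[j] - p[i]) <= max_offset) {
      cnt <- cnt + 1L; cost <- cost + abs(e[j] - p[i]); j <- j + 1L
    }
  }
  c(cnt, cost)
}

# Lexicographic dynamic program: maximize pair count, then minimize total
# |offset|, over monotone one-to-one matchings with |p_i - e_j| <= max_offset.
monotone_match <- function(p, e, max_offset) {
  n <- length(p); m <- length(e)
  C <- matrix(0L, n + 1L, m + 1L)   # pair count
  W <- matrix(0, n + 1L, m + 1L)    # total |offset| at that count
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      c1 <- C[i, j + 1L]; w1 <- W[i, j + 1L]       # skip pen i
      c2 <- C[i + 1L, j]; w2 <- W[i + 1L, j]       # skip ecg j
      if (c1 > c2 || (c1 == c2 && w1 <= w2)) { cb <- c1; wb <- w1 }
      else { cb <- c2; wb <- w2 }
      d <- abs(p[i] - e[j])
      if (d <= max_offset) {
        cm <- C[i, j] + 1L; wm <- W[i, j] + d
        if (cm > cb || (cm == cb && wm < wb)) { cb <- cm; wb <- wm }
      }
      C[i + 1L, j + 1L] <- cb
      W[i + 1L, j + 1L] <- wb
    }
  }
  # traceback (any optimal path; prefer match, then pen-skip)
  pairs <- matrix(0L, 0L, 2L)
  i <- n; j <- m
  tol <- 1e-9
  while (i > 0L && j > 0L) {
    d <- abs(p[i] - e[j])
    if (d <= max_offset && C[i, j] + 1L == C[i + 1L, j + 1L] &&
        abs(W[i, j] + d - W[i + 1L, j + 1L]) <= tol) {
      pairs <- rbind(c(i, j), pairs)
      i <- i - 1L; j <- j - 1L
    } else if (C[i, j + 1L] == C[i + 1L, j + 1L] &&
               abs(W[i, j + 1L] - W[i + 1L, j + 1L]) <= tol) {
      i <- i - 1L
    } else {
      j <- j - 1L
    }
  }
  colnames(pairs) <- c("pen", "ecg")
  list(pairs = pairs, count = C[n + 1L, m + 1L], cost = W[n + 1L, m + 1L])
}

#' Pearson product-moment correlation
#'
#' @param x,y Numeric vectors of equal length >= 2, each with nonzero
#'   variance.
#' @return Correlation coefficient in \[-1, 1\].
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2L)
    stop_param("'x' and 'y' must have equal length >= 2")
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop_data("Pearson correlation undefined for zero-variance input")
  stats::cor(x, y)
}

#' Cosine similarity of two vectors
#'
#' `dot(x, y) / (||x|| * ||y||)`; 1 for parallel vectors, 0 for orthogonal.
#' Computed on raw (uncentered) vectors, so it is origin-dependent.
#'
#' @param x,y Numeric vectors of equal length >= 1; neither all-zero.
#' @return Similarity in \[-1, 1\].
#' @export
cosine_similarity <- function(x, y) {
  if (length(x) != length(y) || !length(x))
    stop_param("'x' and 'y' must have equal positive length")
  nx <- sqrt(sum(x^2)); ny <- sqrt(sum(y^2))
  if (nx == 0 || ny == 0)
    stop_data("cosine similarity undefined for a zero vector")
  sum(x * y) / (nx * ny)
}

#' Mean squared error
#'
#' `(1/n) * sum((y - yhat)^2)`.
#'
#' @param y,yhat Numeric vectors of equal length >= 1.
#' @return Non-negative scalar.
#' @export
mse <- function(y, yhat) {
  if (length(y) != length(yhat) || !length(y))
    stop_param("'y' and 'yhat' must have equal positive length")
  mean((y - yhat)^2)
}

#' Welch's two-sample t-test
#'
#' Unequal-variance comparison of two sample means with Welch-Satterthwaite
#' degrees of freedom and a two-sided p-value. When both samples are exactly
#' constant with equal means the test is degenerate and the conventional
#' `t = 0, p = 1` is returned.
#'
#' @param x,y Numeric vectors, each of length >= 2.
#' @return List with `t`, `df`, `p`.
#' @export
welch_t_test <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L)
    stop_param("each sample must have length >= 2")
  vx <- stats::var(x); vy <- stats::var(y)
  if (vx == 0 && vy == 0) {
    if (mean(x) == mean(y))
      return(list(t = 0, df = length(x) + length(y) - 2L, p = 1))
    return(list(t = sign(mean(x) - mean(y)) * Inf,
                df = length(x) + length(y) - 2L, p = 0))
  }
  ht <- stats::t.test(x, y, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter), p = ht$p.value)
}

#' Full pen/ECG agreement battery
#'
#' Aligns a pen-derived beat series with a reference series and computes the
#' complete agreement report: per-source interval summaries, Pearson and
#' cosine similarity of matched beat timestamps, mean squared error and
#' Welch's t-test of the interval (delta-t) vectors, the mean-heart-rate
#' deviation, an OLS regression of pen timestamps on reference timestamps,
#' and five-number summaries of both interval distributions.
#'
#' Timestamp statistics (Pearson, cosine, regression) use matched pairs
#' only. Interval statistics (MSE, Welch) use intervals between consecutive
#' matched pairs that are adjacent in *both* series, so an undetected or
#' spurious beat drops the affected intervals instead of corrupting them;
#' each source's own summary and five-number spread retain all of its
#' intervals.
#'
#' @inheritParams match_events
#' @param min_matches Minimum number of matched pairs required.
#' @param min_span Minimum span (seconds) each series must cover.
#' @return Object of class `agreement_report`.
#' @export
compare_events <- function(pen, ecg, max_offset = 1, estimate_shift = FALSE,
                           min_matches = 10, min_span = 60) {
  stopifnot(inherits(pen, "event_series"), inherits(ecg, "event_series"))
  for (s in list(pen, ecg)) {
    span <- if (length(s$times) > 1L) diff(range(s$times)) else 0
    if (span < min_span)
      stop_data("event series [%s] spans %.1f s < required %g s",
                s$source, span, min_span)
  }
  mr <- match_events(pen, ecg, max_offset = max_offset,
                     estimate_shift = estimate_shift)
  if (nrow(mr$pairs) < min_matches)
    stop_data("only %d matched beat pairs (< %d); series are not comparable",
              nrow(mr$pairs), min_matches)
  tp <- pen$times[mr$pairs[, 1L]]
  te <- ecg$times[mr$pairs[, 2L]]
  # intervals between consecutive matches that are adjacent in both series
  adj <- diff(mr$pairs[, 1L]) == 1L & diff(mr$pairs[, 2L]) == 1L
  dtp <- diff(tp)[adj]
  dte <- diff(te)[adj]
  sum_pen <- hr_summary(beat_intervals(pen))
  sum_ecg <- hr_summary(beat_intervals(ecg))
  reg <- timestamp_regression(tp, te)
  structure(list(
    hr_summary_pen = sum_pen,
    hr_summary_ecg = sum_ecg,
    pearson_r = pearson_r(tp, te),
    cosine_similarity = cosine_similarity(tp, te),
    mse_dt = mse(dte, dtp),
    welch = welch_t_test(dtp, dte),
    hr_deviation = abs(sum_pen$mean_hr - sum_ecg$mean_hr),
    regression = reg,
    boxplot_pen = stats::fivenum(diff(pen$times)),
    boxplot_ecg = stats::fivenum(diff(ecg$times)),
    median_diff = abs(stats::median(diff(pen$times)) -
                      stats::median(diff(ecg$times))),
    n_matched = nrow(mr$pairs),
    n_unmatched_pen = mr$n_unmatched_pen,
    n_unmatched_ecg = mr$n_unmatched_ecg,
    global_shift = mr$global_shift,
    max_offset = max_offset),
    class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat("Pen/ECG beat agreement\n")
  cat(sprintf("  matched pairs: %d (unmatched: %d pen, %d ecg)\n",
              x$n_matched, x$n_unmatched_pen, x$n_unmatched_ecg))
  cat(sprintf("  ECG:  mean dt %.3f s (sd %.3f), HR %.2f bpm\n",
              x$hr_summary_ecg$mean_dt, x$hr_summary_ecg$sd_dt,
              x$hr_summary_ecg$mean_hr))
  cat(sprintf("  Pen:  mean dt %.3f s (sd %.3f), HR %.2f bpm\n",
              x$hr_summary_pen$mean_dt, x$hr_summary_pen$sd_dt,
              x$hr_summary_pen$mean_hr))
  cat(sprintf("  Pearson R %.6f | cosine %.6f | MSE(dt) %.4g s^2\n",
              x$pearson_r, x$cosine_similarity, x$mse_dt))
  cat(sprintf("  Welch t %.3f (df %.1f), p = %.3f | HR deviation %.2f bpm\n",
              x$welch$t, x$welch$df, x$welch$p, x$hr_deviation))
  cat(sprintf("  timestamp regression: pen = %.4f * ecg %+.4f\n",
              x$regression$slope, x$regression$intercept))
  invisible(x)
}

#' @export
summary.agreement_report <- function(object, ...) {
  print(object)
  cat("  dt five-number summary (s):\n")
  cat("    ecg:", paste(sprintf("%.3f", object$boxplot_ecg), collapse = " "), "\n")
  cat("    pen:", paste(sprintf("%.3f", object$boxplot_pen), collapse = " "), "\n")
  cat(sprintf("  median dt difference: %.3f s\n", object$median_diff))
  invisible(object)
}

#' @export
plot.agreement_report <- function(x, pen = NULL, ecg = NULL, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  lim <- range(c(x$boxplot_pen, x$boxplot_ecg))
  graphics::boxplot(list(ecg = x$boxplot_ecg, pen = x$boxplot_pen),
                    ylab = "dt (s)", main = "interval spread", ylim = lim)
  graphics::plot.new()
  graphics::plot.window(c(0, 1), c(0, 1))
  graphics::text(0.5, 0.5, sprintf("pen = %.4f ecg %+.4f\nR = %.6f",
                                   x$regression$slope, x$regression$intercept,
                                   x$pearson_r))
  invisible(x)
}

#' Write / read an agreement report as JSON
#'
#' Serialization is lossless: numbers are written at full double precision,
#' so `read_report(write_report(x, f))` reproduces every field exactly, and
#' repeated writes of the same report are byte-identical.
#'
#' @param report An [compare_events()] report.
#' @param path Output (input) path.
#' @return `write_report` invisibly returns `path`; `read_report` returns
#'   the restored `agreement_report`.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "agreement_report"))
  x <- unclass(report)
  x$hr_summary_pen <- unclass(x$hr_summary_pen)
  x$hr_summary_ecg <- unclass(x$hr_summary_ecg)
  # 17 significant digits: doubles survive the decimal round trip exactly
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  if (!file.exists(path)) stop_data("report file not found: %s", path)
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$hr_summary_pen <- structure(x$hr_summary_pen, class = "hr_summary")
  x$hr_summary_ecg <- structure(x$hr_summary_ecg, class = "hr_summary")
  structure(x, class = "agreement_report")
}
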