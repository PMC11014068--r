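# Independent reference implementations used to cross-check the package's
# algorithms. These are written naively (plain loops, recursion) and share
# no code with the implementations under test.

# Brute-force peak scan: strict local maxima filtered by height, then
# prominence (walk to the nearest strictly higher sample on each side),
# then greedy tallest-first minimum-separation enforcement.
oracle_peaks <- function(t, a, min_rr, prominence_frac, height_frac) {
  n <- length(a)
  cand <- integer(0)
  for (i in seq_len(n)) {
    if (i > 1 && i < n && a[i] > a[i - 1] && a[i] > a[i + 1])
      cand <- c(cand, i)
  }
  s <- stats::sd(a)
  passed <- integer(0)
  for (i in cand) {
    if (a[i] < mean(a) + height_frac * s) next
    lb <- 1
    for (j in (i - 1):1) if (a[j] > a[i]) { lb <- j + 1; break }
    rb <- n
    if (i < n) for (j in (i + 1):n) if (a[j] > a[i]) { rb <- j - 1; break }
    prom <- a[i] - max(min(a[lb:i]), min(a[i:rb]))
    if (prom >= prominence_frac * s) passed <- c(passed, i)
  }
  kept <- integer(0)
  for (i in passed[order(-a[passed], passed)]) {
    ok <- TRUE
    for (j in kept) if (abs(t[i] - t[j]) < min_rr) ok <- FALSE
    if (ok) kept <- c(kept, i)
  }
  sort(kept)
}

# Optimal monotone matching by memoized recursion over (i, j): maximize the
# pair count, break ties by minimal total |offset|. Returns c(count, cost).
oracle_match_value <- function(p, e, max_offset) {
  np <- length(p); ne <- length(e)
  memo <- new.env(hash = TRUE)
  better <- function(x, y) {
    if (x[1] != y[1]) return(if (x[1] > y[1]) x else y)
    if (x[2] <= y[2]) x else y
  }
  rec <- function(i, j) {
    if (i > np || j > ne) return(c(0, 0))
    key <- paste(i, j)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    res <- better(rec(i + 1, j), rec(i, j + 1))
    d <- abs(p[i] - e[j])
    if (d <= max_offset)
      res <- better(res, rec(i + 1, j + 1) + c(1, d))
    memo[[key]] <- res
    res
  }
  rec(1, 1)
}

# Smooth random test trace: low-pass-ish noise via a short running mean.
random_smooth_trace <- function(n, fs = 50) {
  x <- stats::rnorm(n)
  k <- sample(2:6, 1)
  sm <- stats::filter(x, rep(1 / k, k), sides = 2)
  sm[is.na(sm)] <- 0
  magnitude_trace((seq_len(n) - 1) / fs, as.numeric(sm), fs, stage = "filtered")
}

# Single-subject synthetic pipeline run compared against its ground truth.
run_subject <- function(syn, cutoff = 2) {
  fit <- estimate_heart_rate(syn$recording,
                             filter = butter_lowpass(4, cutoff, syn$recording$fs))
  compare_events(fit$events, syn$truth)
}
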