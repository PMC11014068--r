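test_that("matching pairs identical and uniformly shifted series completely", {
  set.seed(9)
  t0 <- cumsum(runif(40, 0.7, 1.1))
  a <- event_series(t0, "pen"); b <- event_series(t0, "ecg")
  m <- match_events(a, b)
  expect_equal(nrow(m$pairs), 40)
  expect_equal(m$offsets, rep(0, 40))
  expect_equal(m$n_unmatched_pen + m$n_unmatched_ecg, 0)
  m2 <- match_events(event_series(t0 + 0.3, "pen"), b, max_offset = 1)
  expect_equal(nrow(m2$pairs), 40)
  expect_equal(m2$offsets, rep(0.3, 40))
})

test_that("global clock-shift estimation recovers a constant offset", {
  set.seed(10)
  t0 <- cumsum(runif(60, 0.7, 1.1))
  pen <- event_series(t0 + 2.35, "pen")
  ecg <- event_series(t0, "ecg")
  m <- match_events(pen, ecg, max_offset = 0.4, estimate_shift = TRUE)
  expect_equal(nrow(m$pairs), 60)
  expect_lt(abs(m$global_shift - 2.35), 0.05 + 1e-9)
  expect_lt(max(abs(m$offsets)), 0.05 + 1e-9)
})

test_that("matching equals the optimal monotone oracle on random series", {
  set.seed(77)
  for (k in 1:50) {
    np <- sample(3:12, 1); ne <- sample(3:12, 1)
    p <- sort(runif(np, 0, 10)); e <- sort(runif(ne, 0, 10))
    maxoff <- runif(1, 0.2, 1.5)
    got <- penbeat:::monotone_match(p, e, maxoff)
    want <- oracle_match_value(p, e, maxoff)
    expect_equal(got$count, want[1])
    expect_equal(got$cost, want[2], tolerance = 1e-9)
    # returned pairs respect the constraints they were optimized under
    if (nrow(got$pairs) > 1) {
      expect_true(all(diff(got$pairs[, 1]) > 0))
      expect_true(all(diff(got$pairs[, 2]) > 0))
    }
    if (nrow(got$pairs))
      expect_true(all(abs(p[got$pairs[, 1]] - e[got$pairs[, 2]]) <= maxoff))
  }
})

test_that("matching survives random deletions like the oracle says it should", {
  set.seed(31)
  truth <- cumsum(runif(50, 0.7, 1.1))
  keep <- sort(sample(50, 47))
  pen <- truth[keep] + runif(47, -0.03, 0.03)
  got <- penbeat:::monotone_match(pen, truth, 1)
  want <- oracle_match_value(pen, truth, 1)
  expect_equal(got$count, want[1])
  expect_equal(got$count, 47)
  expect_equal(got$cost, want[2], tolerance = 1e-9)
})

test_that("pearson, cosine and mse match hand values", {
  expect_equal(pearson_r(1:5, 1:5), 1)
  expect_equal(pearson_r(1:5, -(1:5)), -1)
  x <- c(1, 2, 3); y <- c(1, 2, 4)
  r_hand <- sum((x - 2) * (y - 7 / 3)) /
    sqrt(sum((x - 2)^2) * sum((y - 7 / 3)^2))
  expect_equal(pearson_r(x, y), r_hand)
  expect_equal(pearson_r(x, y), 0.98198, tolerance = 1e-5)
  expect_error(pearson_r(c(1, 1), c(1, 2)), class = "penbeat_data_error")

  expect_equal(cosine_similarity(c(1, 0), c(1, 1)), 1 / sqrt(2))
  expect_equal(cosine_similarity(c(1, 0), c(0, 1)), 0)
  expect_equal(cosine_similarity(1:4, 1:4), 1)
  expect_error(cosine_similarity(c(0, 0), c(1, 1)),
               class = "penbeat_data_error")

  expect_equal(mse(c(1, 2), c(1, 3)), 0.5)
  expect_equal(mse(1:9, 1:9), 0)
  set.seed(4)
  y1 <- rnorm(30); y2 <- rnorm(30)
  loop <- 0
  for (j in seq_along(y1)) loop <- loop + (y1[j] - y2[j])^2
  expect_equal(mse(y1, y2), loop / 30)
  expect_equal(mse(y1, y2), mse(y2, y1))
  expect_error(mse(1:3, 1:4), class = "penbeat_parameter_error")
})

test_that("Welch test handles identical, shifted and degenerate samples", {
  set.seed(12)
  x <- rnorm(40)
  w <- welch_t_test(x, x)
  expect_equal(w$t, 0)
  expect_equal(w$p, 1)
  w2 <- welch_t_test(c(1, 2, 3, 4), c(1, 2, 3, 4) + 10)
  # formula oracle
  t_hand <- (mean(1:4) - mean(11:14)) / sqrt(var(1:4) / 4 + var(11:14) / 4)
  expect_equal(w2$t, t_hand)
  expect_lt(w2$p, 0.001)
  wd <- welch_t_test(rep(2, 5), rep(2, 7))
  expect_equal(wd$t, 0)
  expect_equal(wd$p, 1)
})

test_that("compare_events on identical series is a perfect report", {
  set.seed(8)
  t0 <- cumsum(runif(90, 0.7, 1.1))
  rep <- compare_events(event_series(t0, "pen"), event_series(t0, "ecg"))
  expect_equal(rep$pearson_r, 1)
  expect_equal(rep$cosine_similarity, 1)
  expect_equal(rep$mse_dt, 0)
  expect_equal(rep$hr_deviation, 0)
  expect_equal(rep$welch$p, 1)
  expect_equal(rep$regression$slope, 1, tolerance = 1e-12)
  expect_equal(rep$regression$intercept, 0, tolerance = 1e-9)
  expect_equal(rep$median_diff, 0)
})

test_that("small timestamp jitter keeps correlation high and Welch null", {
  ok_r <- 0; ok_p <- 0; n_seed <- 100
  for (s in seq_len(n_seed)) {
    set.seed(s)
    truth <- cumsum(runif(100, 0.7, 1.1))
    pen <- sort(truth + runif(100, -0.05, 0.05))
    rep <- compare_events(event_series(pen, "pen"),
                          event_series(truth, "ecg"))
    ok_r <- ok_r + (rep$pearson_r > 0.999)
    ok_p <- ok_p + (rep$welch$p > 0.05)
  }
  expect_equal(ok_r, n_seed)
  expect_gte(ok_p / n_seed, 0.95)
})

test_that("timestamp statistics are invariant to when the truncation happens", {
  set.seed(55)
  truth <- cumsum(runif(80, 0.7, 1.1))
  drop <- sort(sample(80, 76))
  pen <- truth[drop] + runif(76, -0.02, 0.02)
  pen <- sort(pen)
  m <- match_events(event_series(pen, "pen"), event_series(truth, "ecg"))
  tp <- pen[m$pairs[, 1]]; te <- truth[m$pairs[, 2]]
  # computing on matched pairs equals extracting pairs then computing
  expect_equal(pearson_r(tp, te), stats::cor(tp, te))
  expect_equal(cosine_similarity(tp, te),
               sum(tp * te) / sqrt(sum(tp^2) * sum(te^2)))
})

test_that("compare_events guards spans and match counts", {
  short <- event_series(c(0, 1, 2), "pen")
  expect_error(compare_events(short, short), "span",
               class = "penbeat_data_error")
  a <- event_series(seq(0, 100, by = 1), "pen")
  b <- event_series(seq(0.45, 100, by = 1), "ecg")
  suppressWarnings(
    expect_error(compare_events(a, b, max_offset = 0.2, min_matches = 10),
                 class = "penbeat_data_error"))
})
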