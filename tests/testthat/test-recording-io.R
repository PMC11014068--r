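test_that("count files are rescaled affinely and linearly", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("ax,ay,az", "16384,0,0", "8192,16384,-16384"), f)
  rec <- read_pen_recording(f, scale_config(counts_per_g = 16384), fs = 100)
  expect_equal(rec$ax, c(1, 0.5))
  expect_equal(rec$ay, c(0, 1))
  expect_equal(rec$az, c(0, -1))
  # doubling every count doubles every acceleration
  writeLines(c("ax,ay,az", "32768,0,0", "16384,32768,-32768"), f)
  rec2 <- read_pen_recording(f, scale_config(counts_per_g = 16384), fs = 100)
  expect_equal(rec2$ax, 2 * rec$ax)
  expect_equal(rec2$ay, 2 * rec$ay)
})

test_that("implicit time base spans (n-1)/fs", {
  f <- withr::local_tempfile(fileext = ".csv")
  n <- 3000
  utils::write.table(data.frame(ax = rep(16384L, n), ay = 0L, az = 0L), f,
                     sep = ",", row.names = FALSE, quote = FALSE)
  rec <- read_pen_recording(f, fs = 100)
  expect_equal(rec$t[1], 0)
  expect_equal(rec$t[n], (n - 1) / 100)
})

test_that("missing columns and non-monotone time are reported", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("ax,ay", "1,2", "3,4"), f)
  expect_error(read_pen_recording(f), "az", class = "penbeat_format_error")
  writeLines(c("t,ax,ay,az", "0,1,1,1", "0.02,1,1,1", "0.01,1,1,1"), f)
  expect_error(read_pen_recording(f), "increasing", class = "penbeat_data_error")
})

test_that("synthetic recording round-trips through the count format", {
  syn <- generate_recording(synth_config(duration = 5, mean_hr = 70, seed = 3))
  f <- withr::local_tempfile(fileext = ".csv")
  write_pen_recording(syn$recording, f)
  back <- read_pen_recording(f)
  step <- 1 / 16384
  expect_lt(max(abs(back$ax - syn$recording$ax)), step)
  expect_lt(max(abs(back$az - syn$recording$az)), step)
  # generated values are already quantized, so the round trip is exact
  expect_equal(back$ay, syn$recording$ay)
})

test_that("event logs support both RR-interval and timestamp dialects", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("rr_s", "1.0", "1.0", "1.0"), f)
  ev <- read_event_log(f, dialect = "rr")
  expect_equal(ev$times, c(1, 2, 3))
  writeLines(c("time_s", "0.8", "1.6"), f)
  expect_equal(read_event_log(f)$times, c(0.8, 1.6))
  # the two dialects describe the same beat train identically
  beats <- cumsum(c(0.9, 0.85, 1.1, 0.95))
  writeLines(c("t", sprintf("%.17g", beats)), f)
  from_ts <- read_event_log(f)
  writeLines(c("rr", sprintf("%.17g", diff(c(0, beats)))), f)
  from_rr <- read_event_log(f, dialect = "rr")
  expect_equal(from_rr$times, from_ts$times)
})

test_that("invalid event logs raise data errors", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("t", "1.6", "0.8"), f)
  expect_error(read_event_log(f), "increasing", class = "penbeat_data_error")
  writeLines(c("rr", "1.0", "-0.2"), f)
  expect_error(read_event_log(f, dialect = "rr"), "non-positive",
               class = "penbeat_data_error")
  writeLines("rr", f)
  expect_error(read_event_log(f), "empty", class = "penbeat_data_error")
  expect_error(event_series(c(-1, 2)), class = "penbeat_data_error")
})

test_that("agreement reports round-trip losslessly and deterministically", {
  set.seed(42)
  truth <- cumsum(0.8 + 0.03 * rnorm(90))
  pen <- truth + runif(90, -0.02, 0.02)
  rep <- compare_events(event_series(sort(pen), "pen"),
                        event_series(truth, "ecg"))
  f1 <- withr::local_tempfile(fileext = ".json")
  f2 <- withr::local_tempfile(fileext = ".json")
  write_report(rep, f1)
  back <- read_report(f1)
  for (field in c("pearson_r", "cosine_similarity", "mse_dt", "hr_deviation",
                  "median_diff", "n_matched"))
    expect_identical(back[[field]], rep[[field]], label = field)
  expect_identical(back$welch$p, rep$welch$p)
  expect_identical(back$hr_summary_pen$mean_hr, rep$hr_summary_pen$mean_hr)
  write_report(rep, f2)
  expect_identical(readLines(f1), readLines(f2))
})
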