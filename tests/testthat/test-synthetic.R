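test_that("RR series generation honors its contract", {
  # no variability: perfectly periodic train
  ev <- generate_rr_series(60, 0, 10)
  expect_equal(ev$times, 1:10)
  # determinism under seed
  a <- generate_rr_series(75, 0.05, 120, seed = 4)
  b <- generate_rr_series(75, 0.05, 120, seed = 4)
  expect_identical(a$times, b$times)
  expect_true(all(diff(a$times) > 0))
  expect_lte(max(a$times), 120)
  # mean interval concentrates at 60/mean_hr (CLT over ~400 beats)
  hits <- 0
  for (s in 1:100) {
    ev <- generate_rr_series(80, 0.05, 300, seed = s)
    m <- mean(diff(ev$times))
    hits <- hits + (m >= 0.74 && m <= 0.76)
  }
  expect_gte(hits, 95)
})

test_that("a gravity-only configuration yields a ~1 g constant magnitude", {
  syn <- generate_recording(synth_config(duration = 20, mean_hr = 70,
                                         pulse_amp = 0, writing_amp = 0,
                                         sensor_noise_sd = 0, seed = 1))
  m <- magnitude(syn$recording)
  expect_lt(max(abs(m$a - 1)), 1e-3)
})

test_that("noise-free pulses are recovered exactly by the full pipeline", {
  syn <- generate_recording(synth_config(duration = 120, mean_hr = 64,
                                         writing_amp = 0, sensor_noise_sd = 0,
                                         seed = 2))
  fit <- estimate_heart_rate(syn$recording)
  expect_length(fit$events$times, length(syn$truth$times))
  m <- match_events(fit$events, syn$truth)
  expect_lt(max(abs(m$offsets)), 0.01 + 1e-9)
})

test_that("heavy writing noise leaves the beat count within two", {
  cfg <- synth_config(duration = 300, mean_hr = 68, pulse_amp = 0.1,
                      writing_amp = 0.3, seed = 6)  # 3x pulse amplitude
  syn <- generate_recording(cfg)
  fit <- estimate_heart_rate(syn$recording)
  expect_lte(abs(length(fit$events$times) - length(syn$truth$times)), 2)
})

test_that("writing noise is spectrally confined above the 2 Hz cutoff", {
  set.seed(33)
  n <- 30000; fs <- 100
  w <- penbeat:::writing_noise(n, fs, c(4, 8), 0.1)
  spec <- Mod(fft(w))^2
  f <- (seq_len(n) - 1) * fs / n
  f <- pmin(f, fs - f)
  frac_above <- sum(spec[f > 2]) / sum(spec)
  expect_gte(frac_above, 0.9)
  expect_equal(sd(w), 0.1, tolerance = 1e-6)
})

test_that("recordings are quantized to the sensor count grid", {
  syn <- generate_recording(synth_config(duration = 10, mean_hr = 70, seed = 9))
  counts <- syn$recording$ax * 16384
  expect_lt(max(abs(counts - round(counts))), 1e-6)
})

test_that("cohorts are deterministic and order-independent", {
  co1 <- generate_cohort(4, c(54, 84), seed = 11, duration = 15)
  co2 <- generate_cohort(4, c(54, 84), seed = 11, duration = 15)
  expect_identical(co1, co2)
  hrs <- vapply(co1, function(s) s$config$mean_hr, numeric(1))
  expect_true(all(hrs >= 54 & hrs <= 84))
  # regenerating one subject from its own config reproduces it exactly
  redo <- generate_recording(co1[[3]]$config)
  expect_identical(redo$recording$ax, co1[[3]]$recording$ax)
  expect_identical(redo$truth$times, co1[[3]]$truth$times)
  # degenerate range pins the heart rate
  one <- generate_cohort(1, c(60, 60), seed = 2, duration = 15)
  expect_equal(one[[1]]$config$mean_hr, 60)
})

test_that("pipeline recovers mean heart rate within 1 bpm across conditions", {
  ok <- 0; total <- 0
  for (hr in c(55, 65, 75, 85)) {
    for (s in 1:20) {
      syn <- generate_recording(synth_config(duration = 120, mean_hr = hr,
                                             seed = 1000 * hr + s))
      fit <- estimate_heart_rate(syn$recording)
      true_hr <- 60 / mean(diff(syn$truth$times))
      total <- total + 1
      ok <- ok + (abs(coef(fit)["mean_hr"] - true_hr) <= 1)
    }
  }
  expect_gte(ok / total, 0.95)
})

test_that("configuration invariants are enforced", {
  expect_error(synth_config(mean_hr = 30), class = "penbeat_parameter_error")
  expect_error(synth_config(writing_band = c(0.5, 8)),
               class = "penbeat_parameter_error")
  expect_error(synth_config(sdnn = -1), class = "penbeat_parameter_error")
  expect_error(generate_rr_series(400, 0, 10),
               class = "penbeat_parameter_error")
})
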