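# Run code under a temporary RNG state; NULL seed uses the current stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Configuration of a synthetic pen recording
#'
#' Parameterizes the generative model used for validation: a quasi-periodic
#' ballistocardiographic pulse train riding on a 1 g gravity offset, plus
#' band-limited handwriting-motion noise and white sensor noise, sampled at
#' `fs` and quantized to the sensor's count grid. The defaults emulate the
#' acquisition conditions the pipeline targets: five-minute recordings at
#' 100 Hz with resting heart rates.
#'
#' @param duration Recording length, seconds (default 300).
#' @param fs Sampling rate, Hz (default 100).
#' @param mean_hr Mean heart rate, bpm; must lie in \[40, 180\].
#' @param sdnn Standard deviation of RR intervals, seconds (HRV magnitude).
#' @param pulse_amp Peak amplitude of the cardiac pulse before filtering, g.
#' @param pulse_width Full width of the pulse template, seconds.
#' @param writing_band Frequency band of handwriting-motion noise, Hz
#'   `(low, high)`; the lower edge must sit above the cardiac fundamental.
#' @param writing_amp RMS amplitude of the writing-motion acceleration, g.
#'   The stroke waveform acts along one dominant direction (drawn at random
#'   per recording) and is projected onto the three axes.
#' @param sensor_noise_sd White sensor noise standard deviation per axis, g.
#' @param gravity Static gravity magnitude, g.
#' @param orientation Unit 3-vector: pen orientation (direction of gravity
#'   and of the cardiac pulse in the sensor frame).
#' @param rr_ar AR(1) coefficient for successive RR intervals (0 = white
#'   HRV; positive values give slowly wandering rates).
#' @param scale [scale_config()] used for final count quantization.
#' @param seed Integer seed making the recording reproducible.
#' @return Object of class `synth_config`.
#' @export
synth_config <- function(duration = 300, fs = 100, mean_hr = 70, sdnn = 0.05,
                         pulse_amp = 0.1, pulse_width = 0.15,
                         writing_band = c(4, 8), writing_amp = 0.1,
                         sensor_noise_sd = 0.01, gravity = 1,
                         orientation = c(0.36, 0.48, 0.8), rr_ar = 0,
                         scale = scale_config(), seed = NULL) {
  if (duration <= 0 || fs <= 0) stop_param("'duration' and 'fs' must be positive")
  if (mean_hr < 40 || mean_hr > 180)
    stop_param("'mean_hr' must lie in [40, 180] bpm (got %g)", mean_hr)
  if (sdnn < 0) stop_param("'sdnn' must be >= 0")
  if (pulse_amp < 0 || writing_amp < 0 || sensor_noise_sd < 0)
    stop_param("amplitudes must be >= 0")
  if (length(writing_band) != 2L || writing_band[1L] >= writing_band[2L] ||
      writing_band[2L] >= fs / 2)
    stop_param("'writing_band' must be (low, high) with low < high < fs/2")
  if (writing_band[1L] <= mean_hr / 60)
    stop_param("writing band must lie above the cardiac fundamental (%g Hz)",
               mean_hr / 60)
  nrm <- sqrt(sum(orientation^2))
  if (nrm == 0) stop_param("'orientation' must be a nonzero 3-vector")
  structure(list(duration = duration, fs = fs, mean_hr = mean_hr, sdnn = sdnn,
                 pulse_amp = pulse_amp, pulse_width = pulse_width,
                 writing_band = writing_band, writing_amp = writing_amp,
                 sensor_noise_sd = sensor_noise_sd, gravity = gravity,
                 orientation = orientation / nrm, rr_ar = rr_ar,
                 scale = scale, seed = seed),
            class = "synth_config")
}

#' Generate a ground-truth beat series with heart-rate variability
#'
#' Beat times are the cumulative sum of RR intervals drawn from a Gaussian
#' with mean `60/mean_hr` and standard deviation `sdnn`, truncated below at
#' `floor_rr` (redrawn), optionally with AR(1) correlation between
#' successive intervals. Generation continues until `duration` is reached;
#' all returned times lie in `(0, duration]`.
#'
#' @param mean_hr Mean heart rate, bpm.
#' @param sdnn RR standard deviation, seconds; `0` gives a perfectly
#'   periodic train.
#' @param duration Span to cover, seconds.
#' @param seed Integer seed (or `NULL` to use the current RNG stream).
#' @param floor_rr Hard lower bound on RR intervals, seconds.
#' @param ar AR(1) coefficient in \[0, 1) for successive intervals.
#' @return An [event_series()] with `source = "truth"`.
#' @export
generate_rr_series <- function(mean_hr, sdnn, duration, seed = NULL,
                               floor_rr = 0.33, ar = 0) {
  mu <- 60 / mean_hr
  if (mu <= floor_rr)
    stop_param("mean RR (%.3f s) must exceed floor_rr (%.3f s)", mu, floor_rr)
  if (sdnn == 0)
    return(event_series(seq(mu, duration, by = mu), source = "truth"))
  with_seed(seed, {
    times <- numeric(0L)
    total <- 0
    prev_dev <- 0
    innov_sd <- sdnn * sqrt(1 - ar^2)
    while (total < duration) {
      dev <- ar * prev_dev + stats::rnorm(1L, 0, innov_sd)
      rr <- mu + dev
      while (rr < floor_rr) {           # truncated Gaussian: redraw
        dev <- ar * prev_dev + stats::rnorm(1L, 0, innov_sd)
        rr <- mu + dev
      }
      prev_dev <- dev
      total <- total + rr
      if (total <= duration) times <- c(times, total)
    }
    event_series(times, source = "truth")
  })
}

# Cardiac pulse template: raised cosine of full width `width`, shaped by a
# Gaussian window; unit peak at tau = 0, zero outside |tau| <= width/2.
pulse_template <- function(tau, width) {
  out <- numeric(length(tau))
  inside <- abs(tau) <= width / 2
  tt <- tau[inside]
  out[inside] <- 0.5 * (1 + cos(2 * pi * tt / width)) * exp(-8 * tt^2 / width^2)
  out
}

# Writing-motion noise: a constant-amplitude stroke oscillation whose
# instantaneous frequency sweeps [band[1], band[2]] sinusoidally at a slow
# random rate. Handwriting is rhythmic, quasi-periodic stroking, so a slowly
# frequency-modulated tone models it better than filtered white noise -- and
# its constant envelope matters: the Euclidean-magnitude step squares the
# noise components, so envelope fluctuations would be demodulated into the
# sub-2 Hz cardiac band, whereas a constant-envelope oscillation contributes
# only at DC and at twice the stroke frequency. Slow modulation keeps the
# spectrum Carson-bounded near the band with no low-frequency skirt.
writing_noise <- function(n, fs, band, rms) {
  if (rms == 0) return(numeric(n))
  t <- (seq_len(n) - 1L) / fs
  # stroke rhythm drifts across the band over tens of seconds, lingering at
  # the band edges (arcsine dwell of a sinusoidal sweep)
  f_mod <- stats::runif(1L, 0.02, 0.05)        # band sweep rate, Hz
  f_inst <- mean(band) + (diff(band) / 2) *
    sin(2 * pi * f_mod * t + stats::runif(1L, 0, 2 * pi))
  phase <- 2 * pi * cumsum(f_inst) / fs + stats::runif(1L, 0, 2 * pi)
  x <- cos(phase)
  x * (rms / stats::sd(x))
}

#' Generate a synthetic pen recording with known beats
#'
#' Builds the per-axis signal `gravity * u + pulse(t) * u + writing + white`
#' where `u` is the pen-orientation unit vector, the pulse train places one
#' template (see [synth_config()]) at each ground-truth beat time, the
#' writing term is a constant-amplitude stroke oscillation with
#' instantaneous frequency wandering inside `writing_band`, acting along a
#' random dominant stroke direction, and the white term is sensor noise. The result is quantized to the sensor
#' count grid. In the noise-free signal the acceleration magnitude peaks at
#' the ground-truth beat times by construction.
#'
#' @param cfg A [synth_config()].
#' @return Object of class `synthetic_recording`: list with `recording` (an
#'   [accel_recording()]), `truth` (an [event_series()]) and `config`.
#' @export
generate_recording <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  with_seed(cfg$seed, {
    truth <- generate_rr_series(cfg$mean_hr, cfg$sdnn, cfg$duration,
                                seed = NULL, ar = cfg$rr_ar)
    n <- floor(cfg$duration * cfg$fs) + 1L
    t <- (seq_len(n) - 1L) / cfg$fs
    cardiac <- numeric(n)
    half <- ceiling(cfg$pulse_width / 2 * cfg$fs) + 1L
    for (bt in truth$times) {
      c0 <- round(bt * cfg$fs) + 1L
      lo <- max(1L, c0 - half)
      hi <- min(n, c0 + half)
      idx <- lo:hi
      cardiac[idx] <- cardiac[idx] +
        cfg$pulse_amp * pulse_template(t[idx] - bt, cfg$pulse_width)
    }
    u <- cfg$orientation
    # writing strokes move the pen along one dominant direction; a shared
    # waveform across axes keeps the squared terms of the magnitude
    # expansion free of cross-frequency products inside the cardiac band.
    # The held pen is tilted, so stroke motion always couples partly into
    # the gravity axis: fixed 60-degree tilt, random azimuth.
    r <- stats::rnorm(3L)
    v <- r - sum(r * u) * u
    v <- v / sqrt(sum(v^2))
    wdir <- 0.5 * u + sqrt(3) / 2 * v
    stroke <- writing_noise(n, cfg$fs, cfg$writing_band, cfg$writing_amp)
    axes <- lapply(1:3, function(k) {
      u[k] * (cfg$gravity + cardiac) + wdir[k] * stroke +
        stats::rnorm(n, 0, cfg$sensor_noise_sd)
    })
    quant <- function(x) g_to_counts(x, cfg$scale) |> counts_to_g(cfg$scale)
    rec <- accel_recording(ax = quant(axes[[1L]]), ay = quant(axes[[2L]]),
                           az = quant(axes[[3L]]), fs = cfg$fs, t = t,
                           meta = list(device = "synthetic",
                                       mean_hr = cfg$mean_hr))
    structure(list(recording = rec, truth = truth, config = cfg),
              class = "synthetic_recording")
  })
}

#' @export
print.synthetic_recording <- function(x, ...) {
  cat(sprintf("<synthetic_recording> %.0f s @ %g Hz, mean HR %.1f bpm, %d true beats\n",
              x$config$duration, x$config$fs, x$config$mean_hr,
              length(x$truth$times)))
  invisible(x)
}

#' Generate a cohort of synthetic recordings
#'
#' Draws one mean heart rate per subject uniformly in `hr_range` and a
#' distinct sub-seed per subject (both fixed by `seed` before any recording
#' is generated, so recordings are independent of generation order), then
#' generates each subject with [generate_recording()].
#'
#' @param n_subjects Number of recordings.
#' @param hr_range Two-element bpm range for subject mean heart rates.
#' @param seed Master integer seed.
#' @param ... Further overrides passed to [synth_config()] (e.g. `duration`,
#'   `writing_amp`).
#' @return List of `synthetic_recording` objects.
#' @export
generate_cohort <- function(n_subjects = 8, hr_range = c(54, 84), seed = NULL,
                            ...) {
  if (n_subjects < 1L) stop_param("'n_subjects' must be >= 1")
  with_seed(seed, {
    hrs <- stats::runif(n_subjects, hr_range[1L], hr_range[2L])
    sub_seeds <- sample.int(.Machine$integer.max - 1L, n_subjects)
    lapply(seq_len(n_subjects), function(k) {
      generate_recording(synth_config(mean_hr = hrs[k], seed = sub_seeds[k], ...))
    })
  })
}
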