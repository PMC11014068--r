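# penbeat

Heart-rate estimation from the built-in triaxial accelerometer of a digital
writing device.

While a person writes, each cardiac ejection transmits a small
ballistocardiographic pulse through the fingertips into the pen body. A
100 Hz accelerometer near the pen tip records this pulse riding on a ~1 g
gravity offset, buried under handwriting-stroke motion and sensor noise.
`penbeat` recovers the beat train and quantifies how well it agrees with a
reference ECG. It is aimed at wearable-biosignal researchers prototyping
unobtrusive heart-rate monitors and at anyone needing a tested
beat-detection + method-agreement toolchain for accelerometer traces.

## Method

Given raw counts rescaled to g, the pipeline is

1. **magnitude fusion** — a = sqrt(ax² + ay² + az²), orientation-free;
2. **detrend** — remove the quasi-static gravity offset (global mean by
   default);
3. **low-pass filter** — 4th-order Butterworth, 2 Hz cutoff, applied
   forward–backward (zero phase) so beat timestamps are not delayed;
4. **peak detection** — strict local maxima with minimum separation
   `min_rr` (0.33 s), topographic prominence ≥ 0.5 sd and height ≥
   mean + 0.75 sd;
5. **intervals & rate** — the beat-time vector t, its successive
   differences Δt (RR intervals), and HR = 60/Δt in bpm, with
   HR̄ = 60/mean(Δt).

Agreement with a reference beat series uses a monotone one-to-one matching
(max pair count, then minimal total |offset|, offsets ≤ 1 s) and reports:
Pearson r and cosine similarity of matched timestamps, MSE and Welch's
t-test of the interval vectors, the mean-HR deviation, an OLS regression of
pen times on reference times, and five-number interval summaries. A
calibration loop (`scan_cutoffs()`) scans filter cutoffs against a
reference beat count to verify that 2 Hz is optimal.

Because no public recordings exist for this device class, the package ships
a synthetic generator (`generate_recording()`, `generate_cohort()`) with
known ground-truth beats: Gaussian-windowed raised-cosine pulses on a
gravity offset, rhythmic stroke noise confined to 4–8 Hz, white sensor
noise, and count quantization.

## Worked example

```r
library(penbeat)

syn <- generate_recording(synth_config(duration = 300, mean_hr = 72, seed = 42))
fit <- estimate_heart_rate(syn$recording)
summary(fit)
#> Pipeline: magnitude -> detrend(mean) -> Butterworth(order 4, 2 Hz, zero-phase) -> peaks(min_rr 0.33 s)
#> Heart-rate fit: 300 s recording, 360 beats detected
#>   mean HR 72.14 bpm, mean RR 0.832 s (sd 0.053 s)
#>   samples per period: 83.2
#>   RR interval five-number summary (s): 0.670 0.800 0.830 0.870 0.990

compare_events(fit$events, syn$truth)
#> Pen/ECG beat agreement
#>   matched pairs: 360 (unmatched: 0 pen, 0 ecg)
#>   ECG:  mean dt 0.832 s (sd 0.048), HR 72.14 bpm
#>   Pen:  mean dt 0.832 s (sd 0.053), HR 72.14 bpm
#>   Pearson R 1.000000 | cosine 1.000000 | MSE(dt) 0.0002222 s^2
#>   Welch t -0.004 (df 709.6), p = 0.997 | HR deviation 0.00 bpm
#>   timestamp regression: pen = 1.0000 * ecg +0.0015
```

All 360 simulated beats are recovered; the matched timestamps correlate at
r ≈ 1, the interval MSE is ~2×10⁻⁴ s², and the mean heart rate deviates by
less than 0.01 bpm from the ground truth — the same quantities a pen-vs-ECG
bench comparison would report.

A command-line wrapper with `simulate`, `analyze`, `compare` and
`calibrate` subcommands is installed at
`system.file("scripts", "penbeat.R", package = "penbeat")`.

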