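---
title: "Methods: beat detection and agreement analysis for pen-held accelerometers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: beat detection and agreement analysis for pen-held accelerometers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement problem

A pen held between the fingertips carries two acceleration signatures of
interest: a ~1 g quasi-static gravity projection whose direction follows the
grip, and a small ballistocardiographic (BCG) pulse that cardiac ejection
pushes through the fingertips at every beat. On top of these sit
handwriting-stroke motion (large, rhythmic, several Hz) and wideband sensor
noise. The task is to turn a raw triaxial count stream into a beat-timestamp
series (t-vector), inter-beat intervals (Δt-vector), and a mean heart rate
HR̄ = 60/mean(Δt) bpm, and to quantify agreement with a reference ECG beat
series.

The pipeline assumes: uniform sampling at a known rate (100 Hz by default);
a resting, seated writer (heart rate roughly 40–180 bpm, beats at least
0.33 s apart); and stroke motion whose spectral energy lies mostly above the
cardiac band (the resting cardiac fundamental is 0.9–1.4 Hz). Under those
assumptions a 2 Hz low-pass separates pulse from penmanship.

## Pipeline stages and their parameters

**Rescaling.** Counts convert to g affinely,
`g = (counts - offset)/counts_per_g`, with a ±2 g / 16384 counts-per-g
default matching the common configuration of the pen's inertial sensor. The
true full-scale setting of a given device export is often undocumented, so
both numbers are plain configuration.

**Magnitude fusion.** a = sqrt(ax² + ay² + az²) is rotation-invariant, so
grip orientation does not matter. The cost of this convenience is a
nonlinearity: writing in a direction perpendicular to gravity enters the
magnitude only through a squared term |n⊥|²/2g, which demodulates envelope
fluctuations of the stroke motion into low frequencies. This matters for the
synthetic model (below) and is a real failure mode for violently varying
stroke amplitude.

**Detrending.** Peak height and prominence thresholds are meaningful only
after the ~1 g offset is removed. The default is global mean subtraction
(cheap, idempotent); a median and a centered moving mean (window in seconds,
partial windows at the edges, full-trace window ≡ global mean) are available
for drifting grips. The pipeline can also skip detrending (`detrend =
"none"`) to reproduce a bare magnitude → filter chain; since the filter
passes DC, the only practical difference is that the detector's
height threshold then sits relative to the ~1 g mean, which the
mean-relative definition absorbs. We detect on the detrended signal.

**Filtering.** A digital Butterworth low-pass (order 4, cutoff 2 Hz by
default) designed by bilinear transform with pre-warping, so the −3.01 dB
point lands exactly on the cutoff. Application is forward–backward
(zero-phase) by default: a causal 4th-order 2 Hz filter would delay peaks by
a noticeable group delay, breaking timestamp comparisons against ECG;
zero-phase application leaves sub-cutoff peak positions in place at the cost
of squaring the magnitude response (an effective 8th-order rolloff). The
causal single pass is available behind `zero_phase = FALSE`.

Edge handling: each pass starts from the steady state of its first sample
(so constants pass exactly) and the trace is extended by odd
(point-symmetric) reflection of `padlen` samples before the forward pass.
`padlen` defaults to `ceiling(3*fs/cutoff)` — the transient of an IIR
low-pass scales with fs/cutoff, not with the order alone, and three time
constants suffice at double precision. Beats closer than about 1/cutoff to
either trace edge still have degraded timing (their pulse is truncated), and
a beat exactly at the edge cannot be a strict local maximum at all; tests of
one-sample interval recovery therefore assert on interior beats.

**Peak detection.** Candidates are strict local maxima. Three constraints
follow, all relative to the trace's own mean/standard deviation so they
adapt to amplitude:

* height ≥ mean + `height_frac`·sd (default 0.75),
* topographic prominence ≥ `prominence_frac`·sd (default 0.5), where
  prominence is measured by walking to the nearest strictly higher sample on
  each side and subtracting the higher of the two intervening minima,
* minimum separation `min_rr` (default 0.33 s, a ~181 bpm ceiling), enforced
  greedily tallest-first.

The height floor is not redundant with prominence: a noise bump in the
valley between two beats has its prominence measured from the neighboring
valley minima, not from the beat peaks, so it can pass a prominence test
while sitting far below every true peak. On detrended traces the measured
height distributions of true peaks and of noise maxima separate cleanly
between roughly 0.7 and 1.0 sd across the resting heart-rate range, which
fixes the 0.75 default. Peak time is the time of the maximal sample (no
sub-sample interpolation by default; a parabolic refinement is available),
matching tolerances that are set in whole samples.

**Intervals and summaries.** Δt[i] = t[i+1] − t[i]; the summary reports
mean(Δt), its sample standard deviation (an SDNN-like HRV index), HR̄ =
60/mean(Δt) and the beat count. 60/mean(Δt) — the rate whose period is the
mean interval — is used rather than the mean of per-beat rates; the two
differ in the third decimal at resting variability and the package does not
chase that digit.

## Matching and the agreement battery

Two beat series are aligned by the monotone one-to-one matching that
maximizes the number of pairs subject to |pen − (ecg + shift)| ≤ 1 s,
breaking ties by minimal total absolute offset (exact dynamic program; an
optional global clock shift is estimated first by maximizing achievable pair
count over a grid, for recordings made on independently clocked devices —
off by default because synthetic data share one clock). The 1 s window
reflects the observed sub-second pen/ECG peak delays.

From the matched pairs:

* **Pearson r** and **cosine similarity** of the matched raw timestamps
  (cosine on raw, uncentered vectors — it is origin-dependent and reported
  as such);
* **MSE** = mean((Δt_ref − Δt_pen)²) and **Welch's t-test** (two-sided,
  unequal variances, Welch–Satterthwaite df) on intervals formed from
  consecutive matched pairs that are adjacent in *both* series — a missed or
  spurious beat drops the affected intervals instead of corrupting them;
* **per-source summaries** (mean, sd, HR̄) and five-number interval spreads
  over each series' own complete Δt-vector, plus the absolute difference of
  medians and of mean heart rates.

Degenerate inputs have defined behavior: both Welch samples constant with
equal means returns t = 0, p = 1 by convention; zero-variance input to
Pearson, a zero vector for cosine, fewer than 10 matches, or series spanning
under 60 s raise classed data errors rather than propagating NaN.

## Cutoff calibration

`scan_cutoffs()` reproduces the filter-verification loop: for each candidate
cutoff, filter, detect, and score by |detected count − reference count|;
ties break by higher matched-timestamp Pearson correlation, then by the
lower cutoff (stronger noise rejection). The default grid is 0.5–8 Hz in
0.25 Hz steps. Selection is reported per recording, and
`select_cutoff_pooled()` combines scans by summed objective for a
cohort-level choice, so per-subject and global calibration can be compared.
Calibration needs a reference series; it is a validation tool, not a
deployment step.

## The synthetic generator

No raw recordings for this device class are publicly deposited, so every
pipeline stage is exercised on synthetic recordings with known ground truth.
The generative model per axis k is

    s_k(t) = u_k · (g + p(t)) + w_k · A·cos(φ(t)) + ε_k(t)

with u the pen-orientation unit vector, p(t) a train of Gaussian-windowed
raised-cosine pulses (default peak 0.1 g, width 0.15 s) centered on
ground-truth beat times, ε white sensor noise (default sd 0.01 g per axis),
and the middle term the writing motion. Everything is quantized to the
sensor count grid last. Beat times come from cumulated RR draws — truncated
Gaussian, mean 60/mean_hr, sd `sdnn` (default 0.05 s), floor 0.33 s, with an
optional AR(1) option for slowly wandering rates.

Three choices in the writing-motion term deserve explanation:

* **A rhythmic tone, not filtered white noise.** Handwriting is
  quasi-periodic stroking. More importantly, the magnitude step squares
  noise components, so a noise process whose *envelope* fluctuates (as any
  band-limited Gaussian process does, at rates up to its bandwidth) is
  demodulated into 0–bandwidth Hz — inside the cardiac band, where no
  low-pass can remove it. A constant-envelope oscillation instead
  contributes only at DC and at twice the stroke frequency, both outside
  the band of interest.
* **A slow sinusoidal frequency sweep** (0.02–0.05 Hz) across the 4–8 Hz
  band models a writer's drifting stroke rhythm. The slow modulation keeps
  the spectrum confined near the band (fast per-sample frequency jitter
  would act as phase noise and leak Lorentzian skirts into low
  frequencies), and the sweep's arcsine dwell at the band edges means a
  4 Hz cutoff periodically passes sustained stroke energy — which is what
  makes the calibration scan's 4 Hz candidate genuinely degrade, as it
  should.
* **One dominant stroke direction, tilted 60° from the gravity axis**
  (random azimuth per recording). A shared waveform across axes keeps the
  squared magnitude terms free of cross-frequency products between axes,
  and the fixed axial coupling reflects a tilted pen: purely
  gravity-perpendicular strokes would vanish from the magnitude's linear
  term entirely.

`writing_amp` is the RMS of the stroke acceleration vector (default 0.1 g,
equal to the pulse amplitude). The pulse amplitude itself, 0.1 g, models a
firm fingertip coupling at the upper end of the seismocardiography range;
with 0.01 g sensor noise this leaves the filtered pulse roughly eight times
the in-band noise floor, consistent with the visibly clean filtered traces
this class of device produces.

What the generator does **not** emulate: respiratory modulation of the
baseline and of RR intervals, pen lifts and stroke-amplitude bursts (i.e.
envelope demodulation is deliberately absent), grip re-orientation during
writing, ectopic beats, and any stress dynamics. Passing tests on this model
therefore demonstrate correctness of the signal-processing chain under
band-separated interference — not robustness to every behavior of real
handwriting.

Determinism: a configuration seed reproduces a recording exactly; cohorts
draw per-subject heart rates and sub-seeds up front, so each subject's
recording is independent of generation order.

## Numerical choices and test problem sizes

* Filter coefficients come from the bilinear transform with pre-warping;
  |H| is evaluated directly from the transfer function, and tests
  cross-check it against an FFT of the impulse response.
* The matcher's DP cost comparisons use an absolute tolerance of 1e-9 s in
  the traceback; offsets are sums of at most a few hundred sub-second
  terms, far from that tolerance.
* Greedy min-separation resolves height ties by earlier index; the
  brute-force oracle in the tests implements the identical rule.
* JSON reports serialize doubles with 17 significant digits so a
  write–read round trip is bit-exact.
* Default test problem sizes, chosen to exercise asymptotics without waste:
  the agreement cohort runs eight 300 s subjects; the calibration
  selection suite runs twenty 150 s recordings spanning 54–84 bpm; the
  parameter-recovery grid runs 4 heart rates × 20 seeds at 120 s; oracle
  suites use 1000 random short traces (peak detection), 50 random series
  plus 15 series of 30–50 events (matching), and 10⁵ permutations / 1000
  null replicates (Welch).

## Known limitations

* The detector is a fixed-threshold method; it will lose beats when stroke
  envelope fluctuation (which the magnitude demodulates into the cardiac
  band) approaches the filtered pulse height. Matched filtering or
  template tracking would be the next step for hostile recordings.
* Zero-phase filtering is non-causal: the pipeline is an offline analysis
  tool, not a streaming estimator.
* Agreement statistics on raw timestamps (Pearson, cosine) are dominated by
  the common linear trend of time itself and sit near 1 for any two
  plausible beat trains; they are reported for comparability, but MSE of
  intervals and the mean-HR deviation carry the discriminative information.
* HRV reporting stops at the SDNN-like interval standard deviation;
  RMSSD/frequency-domain indices and ectopic-beat handling are out of
  scope.
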