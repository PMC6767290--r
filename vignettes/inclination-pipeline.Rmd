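---
title: "From tilt to millilitres: methods behind the sipsense pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From tilt to millilitres: methods behind the sipsense pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the signal model, every tuning parameter (units,
default, rationale), the numerical choices, and the scope and limits of
the bundled simulator. It is the design record for the package; the README
shows the user-facing workflow.

## 1. Signal model

A triaxial accelerometer is attached to a drinking container with its
x-axis along the container's long axis. When the container moves slowly —
as it does during a deliberate drinking gesture — the measured
acceleration is dominated by gravity, so orientation can be read directly
from the static component:

- **inclination** `θ = atan2(√(ay² + az²), ax)` ∈ [0°, 180°]: the angle
  between the container's long axis and the vertical; 0° upright, 90°
  horizontal;
- **cross-sectional angle** `α = atan2(az, ay)` ∈ (−180°, 180°]: where the
  sensor points within the container's cross-sectional plane.

Both use `atan2`, which is exact and branch-free over the full range.
When the arguments are numerically degenerate (`|a|` below `1e-6` g for θ;
`√(ay² + az²)` below `1e-6` g for α, i.e. the container is upright and α
is genuinely undefined), the previous well-defined value is carried
forward, with 0 as the initial fallback. Carry-forward keeps the angle
series free of jumps that a default like "return 0" would inject into the
rolling statistics downstream.

θ carries the drinking physics: to drink, you tilt the container until
the liquid reaches the opening, and the tilt needed grows as the container
empties. α carries the segmentation signal: it wanders during transport
but is held fixed while liquid is flowing into the mouth.

## 2. Conditioning

`condition()` applies, in order:

1. **Bias removal.** The protocol starts with the container at rest
   upright, so the first `n_init = 50` samples should read (1, 0, 0) g.
   `estimate_bias()` averages them; the mean minus that target is
   subtracted from the whole trace. 50 samples = 2.5 s at 20 Hz, long
   enough to average sensor noise, short enough to stay inside the
   scripted initial rest.
2. **Exclusion intervals.** Operator-marked time windows (protocol
   violations) are deleted before resampling; interpolation then bridges
   the gap from clean neighbours.
3. **Resampling to a uniform 20 Hz grid** by linear interpolation.
   Wireless polling produces jittered, slightly irregular timestamps;
   every downstream window length assumes a fixed rate. Linear
   interpolation is exact for locally-affine signals — a good model at 20
   samples per second of human arm movement — and never overshoots.
4. **Causal moving-average smoothing**, window 2: `y[i] = (x[i−1] + x[i])/2`
   with `y[1] = x[1]`. A light low-pass that suppresses single-sample
   noise without the phase distortion or edge effects of a longer filter.
   Causality means a future streaming implementation behaves identically.

Parameters: `target_rate = 20` Hz (native rate of the target sensor
platform; also the rate all thresholds below are tuned to),
`ma_window = 2` samples.

## 3. Segmentation

### 3.1 Macro-events (whole gestures)

A sample counts as *in motion* when either

- `| ‖a‖ − 1 g | > mag_dev_thresh` (default **0.05 g**) — dynamic
  acceleration on top of gravity; or
- the rolling standard deviation of θ over `theta_std_window_s`
  (default **0.5 s**, centered window) exceeds `theta_std_thresh`
  (default **2°**) — slow reorientation too gentle to move ‖a‖ off 1 g.

Both tests are needed: a slow steady tilt keeps ‖a‖ ≈ 1 g, and a shake in
a fixed orientation keeps θ flat. Maximal motion runs separated by
stillness shorter than `min_still_s` (default **1 s**) are bridged — a
drinker pausing mid-gesture should not split one drink into two — and
surviving runs longer than `min_event_s` (default **1 s**) become
macro-events, numbered in time order. Sub-second blips (adjusting the
bottle, a knock on the table) are rejected by the duration floor.

### 3.2 Micro-events (lift / sip / place)

Within a macro-event, the sip is found from α alone. A sample is
*compliant* when `|Δα| ≤ alpha_diff_max` (default **8°** per sample at
20 Hz, i.e. 160°/s — generous for a hand holding a bottle to the mouth,
far below transport swings). Compliant runs separated by fewer than
`merge_gap = 2` non-compliant samples are merged (a single-sample glitch
should not split a sip); the longest merged run is the sip, ties going to
the earliest. Everything before it is the lift, everything after the
place, so the three phases tile the macro-event exactly. All ranges in the
package are 1-based and half-open (`[start, end)`), the natural indexing
convention in R.

The micro-partition is tested against an exhaustive enumeration oracle
that considers every mergeable group of compliant runs; the two
implementations agree on thousands of random series.

## 4. Features

Per macro-event, `extract_is_features()` computes the 33-dimensional
inclination signature:

- **13 kinematic scalars**: durations of event/lift/sip/place (s), maximum
  θ (deg), relative position of the maximum within the event, θ at sip
  start/end and its sip mean, max/min of the per-sample θ-derivative
  (deg/s), and the time-integrals of θ over the sip and over the event
  (deg·s, trapezoidal rule);
- **10 raw occupancy bins**: fraction of samples falling into each of 10
  exclusive 18°-wide bins spanning [0°, 180°];
- **10 normalized occupancy bins**: the same histogram computed on
  `θ / θ_max` over [0, 1], making the shape descriptor
  amplitude-invariant.

Both histograms are exclusive partitions (each sample in exactly one bin;
the upper boundary closed), so each block sums to one — a property the
test suite asserts. If a degenerate event has `θ_max ≤ 0`, the normalized
histogram is defined as all mass in the first bin, with a warning.

The single-factor benchmarks are `sip_duration`, `integral_theta`
(trapezoidal integral of θ over the sip) and `max_theta`. A `scope`
switch computes the signature over the whole macro-event (default) or the
sip alone.

## 5. Estimation

`model_spec()` + `fit()` wrap ε-insensitive support-vector regression
(`e1071::svm`) and single-factor ordinary least squares (`lm`):

- features are z-scored with parameters learned from the **training rows
  only**, stored on the model and reapplied at prediction (`scale = FALSE`
  is passed to the backend so this is the only standardization);
  zero-variance features are dropped with a warning;
- Gaussian kernel `k(u,v) = exp(−‖u−v‖² / s²)` with named scales
  `medium` (**s = 5.7**) and `coarse` (**s = 23**), plus a `linear`
  kernel. The two scales bracket a mid-range and a deliberately smooth
  regression on 33 standardized features; the coarse kernel suits the
  smoother fill-ratio target;
- unless overridden, `cost = iqr(y)/1.349` and `epsilon = iqr(y)/13.49` —
  the robust-σ convention (IQR/1.349 estimates the standard deviation)
  under which those kernel scales were established. Degenerate
  `iqr(y) = 0` falls back to cost 1 and ε 1e-3.

Validation is **leave-one-trial-out** (`loto_evaluate()`): one fold per
trial, fold-specific standardization, and an audit trail (attribute
`folds`) recording per fold the training trials, training size, and
z-score parameters, so leakage is structurally checkable — the acceptance
suite walks every fold.

Two multi-target strategies couple the volume model to a fill-ratio
estimate: `partition` retrains on the `k_nearest = 150` training drinks
whose fill-ratio labels are closest to the query estimate (ties broken
stably by row order), and `append` adds the fill ratio as a 34th feature,
tagging its provenance (`truth` vs `estimate`) on the model.

## 6. Metrics and aggregation

- `mape()` — mean of per-drink absolute percentage errors (0–100 scale).
- `oape(n)` — absolute percentage error of the *summed* first `n` drinks:
  signed errors cancel in the sum, so OAPE of a sequence can sit below
  every per-drink APE. `moape()` averages OAPE across trials, skipping
  trials shorter than `n` with a warning.
- `residual_volume_estimate()` — `V̂ = β (FR_i − FR_f+1)` with β the
  container's linear density (default 750 mL over the unit fill-ratio
  range, i.e. a straight-walled 750 mL bottle).
- `oape_distortion()` — the closed-form error propagation
  `OAPE = APE / (1 − FR_next)` (APE in fill-ratio units): an endpoint
  fill-ratio error is amplified hyperbolically when little has been
  consumed and passes through unchanged when the container is emptied.
  Undefined at `FR_next = 1` (nothing consumed), which errors.
- `compare_aggregation()` — MOAPE(`n = 11`) of the cumulative (summed
  per-drink predictions) vs residual (endpoint fill-ratio differencing)
  strategies, on identical trial sets; fill-ratio predictions are clamped
  to [0, 1] before conversion since an unconstrained regressor can stray
  outside the physical range. `n = 11` is the longest aggregation span for
  which the drink-12 endpoint estimate exists in a 12-drink protocol.

## 7. The simulator: what it emulates, and what it does not

`sim_config()` defaults *are* the study conditions the package targets —
a scripted protocol of `drinks_per_trial = 12` drinks from a
`capacity_ml = 750` mL straight-walled bottle, 40 subjects × 1 trial,
sampled at 20 Hz.

**Generating laws** (per drink `k`, volume `v`, fill ratios `FR`):

- *tilt law*: `θ_max = θ_base + θ_span · (1 − FR_post) · tilt_k`, capped
  at 170°; defaults `θ_base = 30°`, `θ_span = 60°`. An emptier bottle must
  be tilted further; the cap keeps the gravity reconstruction away from
  the θ = 180° singularity.
- *duration law*:
  `d_sip = (d0 + d_per_ml · v) · (1 + d_fr · (1 − FR_pre)) · dur_k + noise`,
  floored at 1 s; defaults `d0 = 1 s`, `d_per_ml = 0.05 s/mL`,
  `d_fr = 1`. Affine in volume — the signal the duration benchmark
  regresses on — and slowed at low fill levels, where the steeper tilt
  makes liquid flow slower. The `d_fr` term is the volume/fill-level
  confound: it is what makes the duration–volume correlation *sharpen*
  when the analysis is restricted to narrow fill-level bands, the tier
  structure the acceptance suite asserts.
- *volumes*: a small/medium/large Gaussian mixture
  (means 15/35/70 mL, sds 4/8/20 mL, weights 0.50/0.30/0.20, floor 5 mL).
  Most sips are small with a long right tail, giving right-skewed volumes;
  because trials start full and drain slowly, pooled pre-drink fill ratios
  skew toward high values. Trials whose drawn volumes exceed capacity are
  rescaled with a warning.
- *subjects*: log-normal multipliers on tilt (`sd 0.05`), duration
  (`sd 0.18`) and noise (`sd 0.20`) — people differ much more in how fast
  they drink than in how far a given fill level makes them tilt, which is
  geometry. The duration spread is what gives the volume models their
  large between-subject error dispersion relative to fill-ratio models.

**Trajectory construction.** Lift and tilt-up are one continuous raised
cosine from 0 to θ_max (a drinker does not pause mid-air); the sip holds
a raised-cosine envelope with a one-sided, half-rectified sway dip
(`sway_deg = 8°` at `sway_hz = 2.5 Hz`) subtracted — the flat tops leave
θ_max attained over runs of samples, so the 2-sample smoother preserves
it, while the dips keep the rolling-θ-sd motion flag alive through the
hold. α is constant during the sip (by definition of a sip) and carries a
fast wobble (`30°` at `3 Hz`, envelope vanishing at the ends) during
transport so per-sample Δα exceeds the 8° compliance threshold there.
Accelerometer components are reconstructed gravity-only
(`ax = cos θ, ay = sin θ cos α, az = sin θ sin α`) plus per-axis white
noise (`0.01 g`), a per-trial constant bias (`sd 0.005 g`) and ±5 ms
timestamp jitter. Each trial draws an independent seeded substream from
the master seed, so any trial regenerates in isolation.

**Deliberately not emulated**: translational (dynamic) acceleration
beyond what the magnitude threshold needs, non-drinking confounders
(carrying, gesturing, refills), container shape effects on β, sensor
saturation and dropout, and free-living (unscripted) drinking. The
simulator is a test bed for the pipeline's structural claims, not a
substitute for human data; simulated error magnitudes are properties of
the generator.

## 8. Numerical choices

- Trapezoidal quadrature for θ-integrals (exact for the piecewise-linear
  resampled signal), cross-checked against a longhand implementation.
- `atan2` everywhere; no degree/radian mixing (angles are degrees at every
  public interface).
- Stable radix sort underlies nearest-neighbour conditioning, making tie
  handling deterministic.
- CSV round-trips are written at full double precision; reading recovers
  traces to < 1e-9 g.
- All randomness flows from explicit seeds; the same seed reproduces a
  dataset byte for byte.

## 9. Limitations

- The SVR error magnitudes reported on synthetic cohorts track the
  simulator's noise model, not human variability; only orderings and
  structural properties are asserted.
- The micro-partition assumes one sip per macro-event — multi-sip gestures
  collapse to the longest stationary interval.
- β is a single scalar: non-straight-walled containers need a per-shape
  calibration the package does not provide.
- Bias estimation trusts the initial rest; a protocol that starts
  mid-motion needs operator-provided exclusions.
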