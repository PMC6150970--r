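---
title: "Classifying travel mode from accelerometer, GPS and rail-network data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying travel mode from accelerometer, GPS and rail-network data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(travelmode)
```

## The problem and the model

Large cohort studies increasingly collect hip-worn accelerometer and GPS
data for a week at a time. Knowing *when* a participant was walking,
cycling, in a motor vehicle, on a train or stationary turns raw activity
traces into transport outcomes — especially time in active travel, which
is the policy-relevant quantity. `travelmode` classifies every 10-second
epoch independently (no prior segmentation into journeys) with a
five-class gradient-boosted tree ensemble.

The features were chosen because each travel mode leaves a different
physical signature:

* walking produces the largest body acceleration, cycling an
  intermediate amount, and both motorised modes mostly low-amplitude
  vibration;
* vehicles and trains are fast, but vehicles stop at lights while trains
  sustain speed — and only trains run along rail lines;
* metal enclosures (and buildings) attenuate satellite signal, so the
  summed satellite signal-to-noise ratio (sumSNR) drops in vehicles and
  trains and collapses underground, where GPS is often lost altogether.

Epochs are classified by the mode with the highest predicted
probability; exact ties (which essentially never occur with continuous
probabilities) resolve to the earlier mode in the canonical order walk,
cycle, vehicle, train, stationary.

## Epoch features and their estimators

Raw tri-axial acceleration (g units, default 30 Hz) is summarised per
epoch and axis as:

| feature | definition | notes |
|---|---|---|
| `mad_*` | median(&#124;v − median(v)&#124;) | no 1.4826 consistency factor — the plain median absolute deviation from the median |
| `p10_*`, `p90_*` | type-7 (linear interpolation) quantiles | the R default definition |
| `skew_*` | g₁ = m₃ / m₂^{3/2} | moment estimator; 0 for zero-variance input |
| `kurt_*` | g₂ = m₄ / m₂² − 3 | excess kurtosis, same convention |
| `fftmean_*` | mean one-sided DFT magnitude of the mean-subtracted signal, normalised by n | excluding DC keeps the constant gravity component out of the feature |

The estimator choices (moment vs adjusted skewness, excess vs raw
kurtosis, quantile type) only shift feature scales; tree ensembles are
invariant to monotone rescaling, so any consistent convention works.
They are fixed and documented here so results are bit-reproducible.

The epoch grid is anchored at UTC 10-s boundaries (timestamps floored).
Epochs with fewer than half the expected samples are dropped. The first
GPS fix falling inside `[epoch_start, epoch_start + 10 s)` supplies the
epoch's position, speed and satellite set; devices logging every 10 s
make multiple in-epoch fixes rare, and taking the first is deterministic.
Speed prefers the device's Doppler-derived value and falls back to the
haversine distance from the previous fix over the elapsed time.

Distance to the rail network is computed per query point: the network is
projected into a local equirectangular frame anchored at the point
(x = RΔλ·cos φ₀, y = RΔφ, R = 6 371 km) and the minimum clamped
point-to-segment distance is taken over all segments. At the ≤ 10 km
scale of these queries the projection's error against the great-circle
distance is under 0.5% (asserted in the tests), so no GIS dependency is
needed.

## Non-wear detection

Following the GGIR convention for raw data, 60-minute windows advance in
15-minute steps; a window is non-wear when the per-axis standard
deviation is below 13 mg on at least two of three axes, and the flagged
set is the union of qualifying windows. Epochs wholly inside flagged
intervals are excluded from the feature matrix. The step size is not
fixed by the convention's description; 15 minutes is the commonly used
value, and flag edges are therefore quantised to that grid.

## Window smoothing

Travel is locally bursty — cars stop at lights, walkers wait at
crossings, train GPS drops out — so each epoch feature (the 18 per-axis
accelerometer summaries and speed) is smoothed over a **centred**
4-minute moving window: mean, SD, 10th and 90th percentile, plus the
window means of sumSNR and rail distance, and the distance travelled
over the previous and next minute. A centred window is consistent with
the deliberate use of both past ("previous minute") and future ("next
minute") context; windows shrink at the edges of a contiguous run and
never cross a gap in the epoch grid, so device-off periods are not
smoothed over. Statistics are computed over the per-epoch derived
features, not the raw samples. Epochs without GPS contribute only their
accelerometer features; GPS-derived values stay missing and the tree
learner routes missing values natively (no imputation), with
`require_gps = TRUE` available for hard filtering instead.

`window_size_sweep()` reproduces the window-length selection procedure:
candidate windows (1–5 min) are scored on held-out participants by the
mean of walk and cycle F1 — the active-travel modes the smoothing is
meant to help most — and the argmax is selected.

## The classifier

Hyperparameters default to a conservative setting aimed at limiting
overfitting: learning rate (eta) 0.1 instead of the 0.3 default,
200 boosting rounds, row subsampling 0.2 so each tree sees 20% of the
data, maximum depth 10, and minimum split loss (gamma) 10. Class
imbalance is left unweighted — stationary time dominates real data and
the evaluation metrics surface this rather than hide it. Training is
single-threaded by default, which makes fixed-seed runs reproducible at
the label level (the determinism contract the tests assert); parallel
training is possible via `nthread` but excluded from that contract.

Cross-validation is at the participant level: people, not epochs, are
shuffled into five folds (seeded, round-robin after a shuffle), so the
reported accuracy is generalisation to unseen people, not interpolation
within a person's day.

## The simulator: what it does and does not show

`simulate_cohort()` generates the study conditions the package is tested
under: by default 10 participants × 2 commute days. A day is a fixed
schedule of mode segments (150 min: stationary 20, walk 15, train 25,
walk 10, stationary 30, vehicle 20, cycle 15, stationary 15), with a
75-minute non-wear block appended on half the days in expectation.
Training data in commuter studies are extracts around commutes rather
than full days, which is why a simulated "day" is a few active hours.

Per-mode regimes (all configurable via `sim_config()`):

* **speed**: stationary ≈ 0, walk ~5 km/h, cycle ~16 km/h, vehicle ~40
  km/h with stop–go episodes, train ~55 km/h constrained to the rail
  polylines (entering at the nearest point, bouncing at line ends);
* **accelerometer texture**: gravity (1 g) on the z axis plus mode-
  specific oscillation — walking large (~0.35 g at 2 Hz), cycling
  moderate, vehicle and train the *same* low-vibration texture: a
  hip-worn device inside either metal box looks alike, so the motorised
  modes are separated by speed pattern, rail distance and SNR, exactly
  the cues the negative control removes. Worn-but-stationary signal
  includes short postural-adjustment ("fidget") bursts every ~30 s;
  without them, worn-sedentary time would be statistically
  indistinguishable from a removed device and non-wear detection would
  be ill-posed at window edges — real wear data contain this movement.
  Non-wear itself is near-constant output (SD ≈ 0.3 mg);
* **satellites**: open-air modes track ~9 satellites at ~38–40 dB-Hz;
  vehicle ~6 at ~28; train ~5 at ~24 with 30% fix dropout (underground
  stretches are emulated as missing fixes, exercising the pipeline's
  missing-GPS path); indoor stationary ~4 at ~22 with 35% dropout.

Everything derives from one master seed (participant streams get
sub-seeds), so runs are bit-reproducible.

What passing the synthetic recovery tests shows: the pipeline is wired
correctly end to end, the features carry the intended contrasts, and the
classifier can exploit them. What it does not show: performance on real
data, where mode textures overlap far more (slow cycling vs brisk
walking, trams vs buses), GPS urban-canyon noise is structured, and
label noise exists. The near-perfect synthetic accuracies should be read
as an integration check, not a performance claim. The negative control
(`degrade_contrasts = TRUE`) makes vehicle and train identical in speed
and SNR and takes trains off the rails; the resulting collapse of
train/vehicle separation (a ≥ 20-point train sensitivity drop) confirms
the rail-distance and sumSNR features are what separates the motorised
modes, rather than some simulator artefact.

## Numerical choices and degenerate inputs

* Zero-variance epochs: skewness and kurtosis return 0 by convention
  (rather than NaN), keeping constant signal usable in the matrix.
* Undefined metrics (a mode never predicted / never observed) are NA,
  never 0, and any mean over them is NA — silent deflation is worse than
  a missing number. Percentages are rounded (half-up, 1 d.p.) only in
  the report rendering; internal values keep full precision.
* Device files: timestamps are written with 4 sub-second digits so the
  declared-rate check (observed median interval within 1% of the
  declared rate) is robust to text round-tripping; malformed data rows
  are skipped and counted, never fatal.
* The feature table serialises floats to 9 decimals — lossless at the
  scale of every feature (g, km/h, dB-Hz, m).
* Problem sizes in the tests (10 × 2 simulated days for recovery, 5 × 1
  for determinism, 100-instance oracle sweeps) were chosen to exercise
  every code path at cohort-like scale while keeping the default test
  run in minutes.

## Known limitations

* Only five modes; buses are "vehicle" (a rail-adjacent bus can resemble
  a train in every feature), and jogging folds into walking.
* No journey segmentation or temporal post-smoothing of predicted
  labels; epoch independence is a design choice inherited from the
  method, and mode-shift boundaries remain the hardest epochs.
* The rail-distance feature needs rail geometry of reasonable accuracy;
  the GeoJSON reader accepts any WGS84 line layer.
* Timestamps are treated as UTC with an optional fixed per-file offset;
  there is no time-zone database handling.
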