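---
title: "Pre-movement neural dynamics: models, parameters and validation"
author: "premove package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pre-movement neural dynamics: models, parameters and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(premove)
```

## The scientific problem

Self-initiated actions — movements produced without any external cue — are
preceded by slow changes in cortical activity. In head-fixed mice performing
a self-initiated, water-rewarded lever-pull task while dorsal cortex is
imaged with a widefield calcium indicator at 30 Hz, the upcoming pull can be
decoded from area-level activity several seconds before movement, the phase
of slow (0.2–0.6 Hz) cortical oscillations at pull time is strongly biased,
the occupied region of neural state space contracts toward the pull, and
across-trial variance changes seconds before it. `premove` implements that
full analysis chain as a reusable, tested pipeline, driven by a synthetic
session generator with recorded ground truth, so every statistic can be
validated by parameter recovery without access to real recordings.

The pipeline consumes *area-level* time series (e.g. ten bilateral
components for retrosplenial, somatosensory-barrel, somatosensory-limb,
visual and motor cortex, as produced upstream by an atlas-aligned
decomposition such as locaNMF). Pixel-level imaging, atlas registration and
the decomposition itself are out of scope.

## Conventions

All event times are seconds from session start, as doubles. Frame index
`i` (0-based) corresponds to time `i / fps`; peri-event time `t = 0` is the
event; windows are half-open `[t_start, t_end)` in frames. Events detected
on 15 Hz video are stored in seconds and mapped to the nearest neural frame
at extraction time. One convention everywhere prevents off-by-one drift
between modules.

The on-disk session container is a directory holding `neural.csv`
(frames × areas), `events.csv` (`time_s,kind`), `tracks.csv`
(per-feature x/y pixel traces) and `meta.json` (rates, labels, free-form
metadata including the generator's ground truth). Doubles are written with
17 significant digits so round trips are exact and writes are byte-stable.

## The synthetic session generator

`generate_session()` emulates the statistical structure the analysis
assumes. Per area the background is

* a slow sinusoid with a session-fixed frequency drawn uniformly in
  0.2–0.6 Hz (the band in which real session spectra peak), with
  area-dependent amplitude — limb cortex 0.10 a.u., ten times visual cortex
  (0.01), motor 0.06, others 0.04; and
* mean-reverting Ornstein–Uhlenbeck noise (time constant 1 s, stationary
  sd 0.025). Real widefield traces are smooth and oscillation-dominated at
  the single-trial level, so the limb-cortex oscillation SNR is about 4;
  white noise would be both unrealistically rough and unrealistically easy
  to filter out.

Rewarded lever pulls form a Poisson train (0.03 Hz, ≈ 40 pulls per 1330-s
session, matching per-session medians of the task) thinned to a 3-s
refractory lockout. Unrewarded pulls, licks (with a consummatory burst
after each reward) and spontaneous paw-movement bouts complete the event
table; right-paw bouts co-occur with every lever pull (it is the pulling
paw), and body-part tracks at 15 Hz carry those bouts as half-sine
displacements over jittered baselines.

Locked to each rewarded pull, three kinds of structure are implanted from
`signal_onset_s` (default −5 s, when motor-cortex inhibition begins):

1. **Phase concentration.** The area oscillation is cross-faded into an
   event-locked sinusoid whose phase at `t = 0` is a von Mises draw
   (`phase_mu`, `phase_kappa`). The cross-fade is a continuous phase pull
   completing within the first ~15 % of the pre-event window (≈ 0.75 s for
   the default onset): the trace stays smooth — an abrupt phase reset would
   hand the decoder an unrealistic discontinuity — while most of the final
   5 s is an exact event-locked sinusoid, so the implanted phase is the
   quantity the −5..0 s sinusoid fit should recover. After the event the
   oscillation releases back to the background over 1.5 s.
2. **Inhibitory ramp.** A half-cosine from 0 at `signal_onset_s` to
   `-ramp_depth` at `t = 0` in motor and limb cortex (default depth 0.05),
   released over 1 s post-event — the single inhibitory phase seen before
   locked-out rewarded pulls.
3. **Variance change.** The OU noise sd is multiplied by
   `var_change_factor` (default 0.5) from `var_change_onset_s` (default
   −3 s) to the event.

`signal_onset_s` is defined as the ground-truth *decodability* onset: the
implementation is deliberately front-loaded (fast cross-fade) so that
decodable structure is present from the nominal onset rather than drifting
in late, which is what the EDT recovery experiments verify. All implanted
parameters, including the per-event phase draws, are stored in
`meta$ground_truth`, so recovery tests need no side channel.
`generate_null_session()` keeps the identical background and event trains
but implants nothing; it is the negative control throughout.

What the generator does *not* emulate: hemodynamic artifacts, indicator
bleaching and other longitudinal non-stationarities, lick microstructure,
pixel-level spatial structure, and cross-area phase diversity (the implanted
target phase is shared across areas). Passing recovery tests therefore show
the *estimators* are correct and well calibrated on data with the assumed
structure — not that real recordings satisfy those assumptions.

## Preprocessing

Raw traces are band-pass filtered 0.1–6 Hz (4th-order Butterworth,
forward–backward, so zero phase), which doubles as dF/F0 by removing the
baseline; a sliding-baseline dF/F0 (`compute_dff()`, baseline = the window
of the same length immediately preceding the analysis window, e.g. −6..−3 s
for a ±3 s window) is available behind a flag. The two were found
statistically indistinguishable for this analysis, so band-pass is the
default path.

Because `signal::filtfilt` starts from zero state and leaks multi-second
transients at slow corners, zero-phase filtering here wraps it with
odd-reflection padding (about three corner periods) and a first-value/DC
offset; constants pass through exactly.

Causal low-pass filtering (for decoding with filtered features) applies one
forward pass and then advances the output by `round(fps / fc)` samples —
100 samples at 0.3 Hz and 30 fps — padding the tail with the last value.
Note this printed correction rule over-corrects: the true group delay of the
4th-order filter at 0.3 Hz is ≈ 43 samples, so the corrected causal output
*leads* the zero-phase output by ≈ 57 samples. The rule is kept as stated
(it is part of the published procedure); the unit tests freeze the measured
lead so the behavior is explicit.

Trials are extracted as `[n_trials × n_features × n_frames]` tensors with
provenance; control triggers are uniform random times at least 3 s from any
lever pull (so controls may legitimately contain other behaviors — a
conservative control). PCA denoising fits frames-as-samples bases at ≥ 95 %
explained variance per session; behavior and control sets of one session
share one basis. Multi-session concatenation denoises each session, fits a
shared basis on a seeded 3 % sample of the concatenated frames, and projects
everything onto a fixed 20 components (capped at the feature dimension —
synthetic sessions have 10 areas, so 10).

## Decoding and the EDT

For every evaluation time `t`, a sigmoid-kernel SVM (cost 1, kernel
coefficient `1/(n_features · var)`, the only kernel the procedure fixes)
classifies behavior vs control trials from the flattened features in
`[t − 1 s, t)`; accuracy is assigned to the window's last time point, so a
±15 s window at 30 fps yields 870 per-timepoint classifiers per fold.
Folds are stratified, seeded and shared across time points, making fold
accuracies paired in time. Curves are smoothed with a 30-step (1-s) moving
average per fold, each time point is tested against chance with a
one-sample t-test over the fold accuracies (two-sided, as in the reference
implementation of the procedure; a zero-variance time point gets p = 0 or 1),
and Benjamini–Hochberg correction is applied across *all* time points of
the curve. The **earliest decoding time** is then found by walking backward
from `t = 0`: the EDT is the start of the contiguous significant run ending
at 0; isolated earlier significant islands are ignored, and a
non-significant `t = 0` means EDT = 0, "not predicted". Whether the t-tests
should see smoothed per-fold traces or a smoothed mean with raw folds is
not fixed by the procedure's description; this implementation smooths per
fold, which keeps the fold pairing intact.

## Phase analysis

Single-trial sinusoids `A sin(2πf t + φ) + c` are fit over −5..0 s by
Levenberg–Marquardt least squares. Over five seconds such a fit is
unidentifiable without frequency constraints, so it multi-starts over
f ∈ {0.1, …, 1.0} Hz (bounds 0.05–2 Hz), with amplitude and phase
initialized by linear regression on sin/cos components at each start; the
best-RMSE start wins, and the phase at `t = 0` is `wrap(φ) ∈ (−π, π]`.
Circular statistics use trigonometric moments; the Rayleigh test uses the
standard finite-n corrected formula, whose p values are verified uniform
under uniform phases. Inter-area phase association uses the Fisher–Lee
circular–circular correlation — plain Pearson on wrapped angles is wrong at
the ±π seam.

Power spectra use Welch's method (mean-removed Hann segments of
min(n, 512) samples, 50 % overlap), normalized so the one-sided density
integrates to the signal variance. No installed R package provides Welch's
estimator, so it is implemented directly and checked against closed-form
sinusoid power. Longitudinal trends are Pearson correlations against the
session ordinal with an optional burn-in (dropping the first week of
training removes habituation idiosyncrasies).

## Convex-hull state space

All hulls of a session are computed in one shared embedding (the top
principal components of the session's frame vectors): hull volumes are
basis-dependent, so ratios are only meaningful in a common basis. The
embedding dimension defaults to 3 — hull volume in the full component space
is combinatorially infeasible, the published analysis visualizes in 2-D and
computes a "hyper-volume" without fixing a dimension, and 3 is the largest
dimension for which an exact, dependency-free hull is practical here
(2 is also supported). Hulls use `grDevices::chull` in 2-D and an
incremental quickhull in 3-D with an exact interior-point pre-filter
(points inside the hull of directional extremes cannot be vertices);
volumes were verified against analytic solids, Monte-Carlo rejection, and
an external qhull implementation.

Because hulls are outlier-sensitive, a 10 % k-nearest-neighbor triage
(k = 10; the neighbor count is this package's choice) removes the most
isolated points before every hull. The ratio curve divides the hull volume
of the 1-s segments ending at offsets −10..0 s (all frames of all trials)
by the hull volume of the whole session (a seeded subsample of at most
4000 frames keeps the denominator tractable); ratios are clamped to [0, 1]
since triage is applied to numerator and denominator separately. The
normalized AUC divides the trapezoidal area under the event-locked curve by
that of a random-trigger curve (triggers ≥ 3 s from rewarded pulls,
re-sampled over repetitions). Hull overlap between two behaviors is a
Monte-Carlo estimate — uniform samples inside hull(A) by rejection, fraction
inside hull(B) — reported in both directions plus the symmetrized mean.

## Variance change (EVDT)

The across-trial variance trace of an area is thresholded against a
pre-event baseline (mean and sd of the variance over −30..−15 s): the EVDT
is the earliest time from which *every* sample in a 1-s sliding window
(one-frame step, left-closed) stays below `mean − k·sd` (decrease mode;
`k = 2` by default, with 2 vs 4 giving somewhat different distributions —
the statistic is threshold-sensitive by design), or beyond `k·sd` in
absolute value (absolute mode, for subjects whose pre-movement variance
increases). Detections outside −6..+0.5 s are discarded. A globally
constant trace is reported "undetected" (it can never cross a strict
threshold); a varying trace over a zero-sd baseline is a degenerate-baseline
error. Savitzky–Golay smoothing (31 samples) of the variance trace is
available for noisy areas. EVDT is intended for non-lockout trial sets;
pooled lockout sets carry much higher intra-session variance and
`session_evdt()` is not meaningful there.

## Behavioral rules

Movement initiations are upward crossings of `k_std` times the whole-session
speed sd on smoothed tracks (30-frame sliding mean or Savitzky–Golay 31/3),
with a 3-s refractory rule. Both `k_std = 3` and `k_std = 1` are in use in
different parts of the published analysis; the default here is 3 and the
multiplier is a parameter. Lockouts are evaluated on a 0.250-s bin grid,
with the first bin of the lockout span and the bin immediately before the
event allowed to contain movement (video-resolution tolerance). Locked-out
trials pool into overlapping groups of at most 200 with a 50-trial stride,
emitting windows while at least 50 trials remain — this reproduces the
published 503-trial enumeration (10 groups, 0–200 … 450–503) exactly,
including trailing windows that share an end. Quiescent-bout selection
keeps body-movement initiations with no lever pull within −15..+5 s and no
body movement in the preceding 5 s, recording the quiescence duration for
raster ordering.

## Validation experiments and problem sizes

The `*_recovery_run()` functions are the package's validation surface; the
acceptance script (`scripts/acceptance.R`) and the test suite run them.
Problem sizes are the package's own choices, fixed here:

* **EDT recovery**: implanted onset −4 s, 200 trials per class pooled from
  ≈ 7 sessions in a shared basis, 10-fold cross-validation, trial window
  −6.5..+1.5 s, evaluation grid strided to 5 Hz (curve smoothing spans 1 s
  of that grid). Median recovered EDT over 10 seeds falls in [−5, −3]; the
  half-cosine ramp starts with zero slope, so recovery slightly after the
  nominal onset is the expected behavior, not a bias to be corrected.
* **Null decoding**: 60 trials per class from null sessions; EDT = 0 in at
  least 85 % of 20 runs (the contiguity rule plus BH correction is
  conservative).
* **Phase recovery**: κ ∈ {0, 2, 10, 50}, 10 sessions each, sinusoid fits
  in limb cortex restricted to pulls with no neighboring pull within 6.5 s
  (so neighboring implants and their release transients stay out of the
  fit window — the same logic as the lockout used throughout the published
  analysis). Fitted-phase resultant length increases strictly in κ and
  exceeds 0.9 at κ = 50; uniform-null Rayleigh p values are KS-uniform.
* **EVDT recovery**: variance drop at −3 s, factor 0.5, implanted alone
  (κ = 0, no ramp) and measured in visual cortex where oscillation variance
  is negligible; recovered in [−4, −2] in ≥ 80 % of 10 seeds.
* **Hull suite**: unit-square area, subset monotonicity, self- and
  shifted-cube overlaps, and structured-vs-null normalized AUC (< 1
  structured, ≈ 1 null) with 5 random-trigger repetitions per session.

## Known limitations

* The causal-filter delay correction over-corrects (see above); analyses
  mixing causal and zero-phase features should account for the ~57-sample
  lead.
* The sinusoid fit's phase error grows when the drawn area frequency is at
  the slow end (≈ 0.2 Hz, barely one cycle in 5 s); resultant lengths are
  estimator-limited near ≈ 0.95 even for near-deterministic implants.
* Hull volumes are exact only for d ≤ 3; higher embedding dimensions would
  need a qhull-grade library.
* EVDT detection is threshold-sensitive and was tuned for clean implants;
  on noisy variance traces enable smoothing and expect discards.
* The generator's inter-area structure is simplistic (shared target phase,
  independent noise), so cross-area statistics (e.g. Fisher–Lee phase
  correlations) are validated for calibration, not for realistic effect
  sizes.
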