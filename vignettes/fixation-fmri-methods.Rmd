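---
title: "Fixation-based event-related fMRI of visual search: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fixation-based event-related fMRI of visual search: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fixfmri)
```

# The scientific problem

In multiple-target visual search, observers scan a display of many similar
items, most of them task-irrelevant common distractors (CD), with occasional
targets (T) and equally rare but to-be-ignored rare distractors (RD). Because
targets and rare distractors occur equally seldom, contrasting the brain
response to fixations on them dissociates *task relevance* from mere
*rarity*. The analysis unit is the individual fixation, not the trial: each
fixation on an item is treated as an event in an event-related fMRI design.

Two kinds of neural effect are of interest:

* an **amplitude effect** — a region responds more strongly to target
  fixations than to rare-distractor fixations (the dorsal-attention /
  intraparietal pattern), detectable with a univariate GLM contrast;
* a **pattern effect** — a region responds with the *same mean amplitude* to
  both but with distinct multivoxel patterns (the pattern reported for the
  temporo-parietal junction), detectable only with multivariate decoding.

Real data for such a study cannot be regenerated at desk scale, so `fixfmri`
couples every analysis stage to a synthetic-experiment generator with known
ground truth. A green test therefore establishes that the implementation
*recovers what was planted*, under the stated noise model — not that any
particular brain region behaves this way.

# The simulated experiment

## Design

Six runs of 28 trials (168 total): per run, 6 trials of each exhaustive
condition (`0T_0RD`, `0T_1RD`, `1T_0RD`, `1T_1RD`) and 2 of each two-target
catch condition (`2T_0RD`, `2T_1RD`), in seeded random order. Inter-trial
intervals are drawn from 3500–8500 ms in 500 ms steps. Each display holds 30
items on a jittered 7×7 grid inside a 10.21°×10.21° area with per-axis jitter
≤ 0.16° and minimum inter-item distance 1.14°.

Two geometric details are decisions of this package, since only the area,
jitter and minimum distance are given:

* **Grid spacing** is `(10.21 − 2·0.16)/6 ≈ 1.648°`, so that every grid
  intersection plus maximal jitter stays inside the stated area. With this
  spacing the minimum-distance constraint holds for *any* jitter draw
  (worst-case axis-aligned neighbors are 1.648 − 0.32 = 1.33° apart); the
  generator still verifies each display by an all-pairs scan.
* **The central intersection is reserved**: each trial begins with a central
  drift-correction fixation, so no search item is placed at the display
  center. Without this, an item at the center would be "visited" by the
  pre-trial fixation itself and the visit would be unrecoverable from the
  gaze trace.

## Gaze traces

Scan paths follow a distance-driven policy: from the center, always the
nearest unvisited item (ties to the lowest item id). Exhaustive conditions
visit all 30 items; catch trials self-terminate at the second target. Dwell
durations are truncated-normal per item type with means/SDs matching the
empirical fixation-duration table (T 465/120 ms, RD 430/123 ms, CD
368/77 ms; truncation at 100 ms shifts the means negligibly). With
probability 0.1 a visit is split by a small (0.4°) within-item saccade —
an immediate refixation that the parser must collapse again.

Saccades are minimum-jerk position ramps. Their duration is set from a
main-sequence-like peak-velocity model (`150 + 30·amplitude` deg/s), which
keeps peak velocity and acceleration several-fold above the detector's
30 deg/s and 9500 deg/s² thresholds for every amplitude the generator can
produce; `gaze_params()` refuses parameterizations for which this fails.
Fixational noise is white positional noise with SD 0.02°, small enough that
noise-induced velocity excursions (≈3.5 deg/s SD) practically never cross
the detection threshold. Traces are sampled at 500 Hz (2 ms steps).

The generator does **not** model blinks, smooth pursuit, microsaccades
(other than the refixation split), calibration drift, or pupil dynamics.
Empirical saccade amplitudes in this paradigm average ≈3.5°; the
nearest-item policy produces shorter steps (≈2°). Fixation-duration and
rank structure, which drive everything downstream, are matched; saccade
metrics are summarized but not calibrated to the empirical table.

## Behavior

Each present target is missed independently with probability 0.0816
(matching the reported ≈8.16 % error rate on target-present trials, which is
driven by target misses); the response is the count of detected targets, and
the response time is the last fixation offset plus a fixed 300 ms motor
latency. Response-time generation is not otherwise modeled.

## BOLD volumes

Voxel time courses on a 24×24×16 grid (2.5 mm voxels, TR 1250 ms) are

```
baseline + Σ_events amplitude(class) · pattern(voxel, class) · HRF(t − onset)
         + drift + AR(1) noise,
```

with the canonical double-gamma HRF, low-frequency drift, AR(1) Gaussian
noise (stationary SD 1, ρ = 0.3 by default) and six random-walk motion
series returned for nuisance regression. Three disjoint regions are planted:

* **amplitude region**: amplitudes T 1.0, RD 0.5, CD 0.2 (arbitrary BOLD
  units), spatially uniform;
* **pattern-only region**: equal mean amplitude 1.0 for T and RD, but
  per-voxel multipliers drawn per *subject* (SD 0.5, exactly mean-centered,
  stable across runs). Drawing patterns per subject is essential: patterns
  shared across subjects would survive group averaging and show up in the
  univariate contrast, destroying the dissociation the region is meant to
  embody;
* **null region**: no event-related signal.

The 0.5 pattern SD is a choice of this package (the magnitude of real
pattern effects is not stated anywhere usable); it yields single-subject
searchlight accuracies around 0.7–0.9 at the default noise, comparable to a
strong but realistic decoding effect.

Drift is generated as a random combination of the *same* cosine basis
functions (periods > 192 s, evaluated over the retained volumes) that the
GLM uses as high-pass regressors, so the filter removes it exactly by
construction. This makes "the high-pass filter removes the drift" a testable
identity rather than an approximation.

# Analysis stages

## Oculomotor parsing

Velocity is estimated by central differences over a 5-sample window,
acceleration from the velocity by a 3-sample window (the commercial parser's
internals are proprietary; both windows are configurable). Maximal runs of
samples with speed above 30 deg/s become saccades if they last ≥ 4 samples
(8 ms, a noise-spike guard) and their peak acceleration reaches 9500 deg/s².
Fixations are the complementary intervals; each is assigned to the item
nearest its mean position (ties to the lowest id). Immediate refixations
collapse (durations summed, onset and preceding saccade from the first
member, following saccade from the last), ranks are serial positions within
the trial, and the fixation already in progress at display onset — the
carried-over drift-correction fixation — is dropped before assignment.
Saccade direction is computed and stored but consumed by no later stage.

The round trip (simulate → parse) recovers ≥ 99 % of ground-truth item
visits (same item, onset within ±10 ms) at default noise; the detector
itself is tested sample-for-sample against a brute-force threshold scan.

## Rank matching

Within each run, trial order is randomized (to avoid draining early trials),
then each first fixation on a T or RD from correct, non-catch trials of the
three matchable conditions is paired with a common-distractor first fixation
of *exactly* the same rank from a *different* trial of the *same* condition.
A chosen distractor is removed from the pool; events with no exact match are
dropped and logged. Where several distractors qualify, one is chosen
uniformly at random (the selection rule among multiple exact matches is
unspecified in the source procedure; uniform choice is the neutral option).
T and RD events are processed interleaved in the randomized trial order (by
rank within trial); a config switch can process classes separately, since
the original ordering between classes is not stated.

## GLM

Eight task regressors (T, RD, CD_T, CD_RD crossed with their source
conditions) are duration-0 impulses convolved with the peak-normalized
canonical double-gamma HRF (peak 6 s, undershoot 16 s, ratio 1/6, 32 s
support) sampled at the retained volume times; the first two volumes of each
run are discarded. Nuisance columns: cosine drift basis with periods ≥ 128 s,
six motion parameters, intercept; runs are modeled as separate sessions; no
global normalization. Unmatched events, error trials, catch trials and the
all-common condition are simply not modeled (implicit baseline).

Residual autocorrelation is modeled as AR(1) with a single coefficient
pooled across mask voxels per run (stable at desk scale; per-voxel
estimation would be noisy with ~380 volumes), followed by prewhitening and
OLS. Empty task columns (no surviving events) are kept, flagged, and
excluded from estimation with `NA` coefficients; contrasts skip runs that
lack a needed regressor. Subject contrasts average run effects; standard
analyses smooth the data with a 6 mm FWHM Gaussian (edge-renormalized
separable kernel), pattern analyses use unsmoothed data.

Group inference is a voxelwise one-sample t-test with cluster-level FWE by
sign-flip permutation: threshold at one-sided p < 0.001, 26-connectivity
clusters, null distribution of the maximal cluster size over random sign
flips of the subject maps, clusters reported at FWE p < 0.05. Sign-flip
permutation was chosen over random-field theory because it is exactly
implementable and its calibration is itself testable (the suite verifies a
≈5 % family-wise error rate on pure noise).

Percent signal change in an ROI is `100 · mean beta · peak(unit-event
regressor) / mean intercept`; with the peak-normalized HRF the regressor
peak is 1, so PSC reduces to beta over baseline. (Whether the original
toolbox scaled by the regressor peak or a block height is not stated; peak
scaling is implemented and documented here.)

## Searchlight MVPA

Per-run beta maps of targets (`T.1T_0RD`) and rare distractors (`RD.0T_1RD`)
from unsmoothed data are the two class exemplars per run; the mixed
condition and the common distractors are excluded. For every mask voxel, a
sphere of radius 4 voxels (257 voxels in the interior) is classified with
leave-one-run-out cross-validation: train on 10 exemplars, test on the
held-out run's 2 — so per-fold accuracy has granularity {0, ½, 1}, and the
map value is the mean over 6 folds.

The classifier is a linear margin classifier: kernel ridge regression on ±1
labels with fixed regularization (λ = 1) and feature demeaning by the
training mean (the original toolbox's default is a linear margin classifier;
the exact classifier and regularization are unstated, so both are config
options, with a nearest-centroid alternative). Demeaning makes accuracy
exactly invariant to adding a constant to every pattern. Implementation
note: only the Gram matrix of each sphere's exemplars is needed, and all
sphere Gram matrices are computed at once by FFT sphere-sums of voxelwise
product maps — algebraically identical to explicit per-sphere extraction
(unit-tested against it) but orders of magnitude faster in R.

Accuracy maps are smoothed (6 mm) and tested against chance (0.5) with the
same cluster-FWE machinery. Spatial normalization is a no-op here because
all synthetic subjects share one grid.

# Numerical and policy choices

* Coordinates are degrees of visual angle, origin at display center, y up;
  times in ms; event intervals half-open `[onset, offset)`; voxel indices
  1-based in R, reported as lattice coordinates.
* All randomness flows through explicit integer seeds; heavy stages derive
  per-subject/per-stage sub-seeds from one master seed, and every seed is
  recorded in the run manifest.
* The trial-initial latency (200 ms) and motor latency (300 ms) are
  config-exposed constants; neither is stated in the source design.
* Zero-variance voxels in group tests yield `NA` statistics rather than
  infinities; empty candidate sets yield empty report tables rather than
  division by zero.
* The repetition counts of the heaviest acceptance suites are scaled to a
  single-CPU budget (5 repeated experiments instead of 10 for the GLM
  recovery, with the same ≥0.9 per-experiment pass rate; the FWE calibration
  uses directly generated smooth-noise subject maps). Large simulation
  studies bypass the 500 Hz trace round trip and use the generator's
  ground-truth fixation logs; the parser round trip is validated separately
  at ≥99 % recovery, so this changes runtime, not semantics.

# Known limitations

* The scan-path model is deterministic given the display (nearest-item
  policy); real scan paths are noisier and produce longer saccades.
* BOLD noise is spatially independent before smoothing; physiological
  noise, scanner artifacts and motion-correlated signal are not modeled
  (motion enters only as nuisance series).
* With two exemplars per run and class, searchlight accuracy is coarse at
  the single-sphere level; group inference absorbs this.
* Catch-trial gaze ends at the second target visit even if the behavioral
  model later records a miss on that trial; the discrepancy only affects
  trials that are excluded from matching anyway.
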