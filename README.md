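# fixfmri

Fixation-based event-related fMRI analysis of multiple-target visual search,
driven entirely by a synthetic-experiment generator with known ground truth.

## The problem

In a multiple-target search task, observers scan 30-item displays containing
frequent common distractors (CD) and rare items that are either targets (T)
or to-be-ignored rare distractors (RD). Treating each **fixation** as an
event lets the BOLD response to fixated item types be compared while holding
rarity constant — but fixations on rare items occur later and in different
temporal contexts than typical distractor fixations, so each T/RD fixation is
compared against a CD fixation **matched on fixation rank** (its serial
position in the trial's fixation sequence).

Two effects dissociate task relevance from rarity:

* **amplitude**: a region responds more strongly to T than to RD fixations —
  detected by the univariate contrast `T − RD` in a canonical-HRF GLM;
* **pattern**: a region responds equally strongly to both, but with distinct
  multivoxel patterns — detected by a searchlight classifier on per-run beta
  patterns with leave-one-run-out cross-validation and a group test of
  accuracy against chance (0.5).

The package implements the full chain:

1. **Synthetic experiment** — session plans (6 runs × 28 trials, jittered
   7×7-grid displays), 500 Hz gaze traces with item-type-specific dwell
   durations, behavioral responses with target misses, and 4-D BOLD volumes
   (TR 1250 ms) with planted amplitude / pattern-only / null regions, cosine
   drift, AR(1) noise and motion series.
2. **Oculomotor parsing** — saccade detection (30 °/s velocity and
   9500 °/s² acceleration thresholds), fixation segmentation, nearest-item
   assignment, collapsing of immediate refixations, fixation ranks.
3. **Rank matching** — exact-rank pairing of first T/RD fixations with CD
   fixations from different trials of the same condition and run, without
   reuse, with a drop log and match-rate report.
4. **GLM** — 8 fixation-event regressors (duration-0 impulses ⊗ canonical
   double-gamma HRF), 1/128 Hz cosine high-pass, 6 motion regressors, AR(1)
   prewhitening, run-wise fits, contrasts, 6 mm Gaussian smoothing,
   second-level one-sample t with cluster-level FWE by sign-flip
   permutation, and ROI percent signal change.
5. **Searchlight MVPA** — radius-4-voxel spheres (257 voxels), linear margin
   classifier, leave-one-run-out CV, accuracy-map smoothing and group test.

## Worked example

One synthetic subject at desk scale (2 runs, 16×16×12 grid):

```r
library(fixfmri)
cfg <- pipeline_config(n_runs = 2, dim = c(16, 16, 12))
sub <- simulate_subject(cfg, seed = 101)

sub$match_report$table
#>   class condition n_total n_matched match_rate_pct
#> 1    RD    0T_1RD      12        12            100
#> 2    RD    1T_1RD      12        12            100
#> 3     T    1T_0RD      12        12            100
#> 4     T    1T_1RD      12        12            100

sub$behavior$by_item_type
#>   item_type    n mean_fixdur_ms mean_prec_sacc_deg mean_foll_sacc_deg
#> 1         T   24       465.3333           1.677173           2.666713
#> 2        RD   24       467.3333           2.456460           2.368859
#> 3        CD 1032       368.5988           2.137411           2.136935

amp <- sub$regions$regions[[1]]$voxels   # planted amplitude region
pat <- sub$regions$regions[[2]]$voxels   # planted pattern-only region
round(psc_by_class(sub$fits_smoothed, amp), 3)
#>     T    RD  CD_T CD_RD
#> 0.789 0.457 0.316 0.238

mean(sub$accuracy[pat], na.rm = TRUE)
#> [1] 1
```

All four T/RD event classes were rank-matched here (small sessions often
match fully; larger simulated sessions show the few-percent losses typical
of exact-rank matching). Mean fixation durations recover the generator's
item-type means (T ≈ 465 ms, CD ≈ 368 ms). Percent signal change in the
amplitude region reproduces the planted ordering T > RD > CD against a
baseline of 100 (ground truth 1.0 / 0.5 / 0.2 amplitude units ≙ 1.0 / 0.5 /
0.2 % of baseline; values are noisy at this scale), and the searchlight
decodes the pattern-only region perfectly within this subject.

The multi-subject group analysis — cluster-level FWE inference on `T − RD`,
the rank-control contrast `CD_T − CD_RD`, and the accuracy-vs-chance test —
runs via `run_pipeline(pipeline_config(), seed = 1, out_dir = "out")`, which
writes cluster tables (TSV), percent signal change and a manifest (JSON),
and `render_report()` summarizes them as Markdown. A thin command-line
wrapper is installed at `inst/scripts/fixfmri-pipeline.R`.

## Acceptance script

`scripts/acceptance.R` regenerates the display-geometry acceptance targets
from scratch with the installed package: it generates 100 displays, computes
the minimum pairwise inter-item distance by all-pairs brute force and the
maximum per-display span of item positions, and writes both as JSON.

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Vignette

`vignettes/fixation-fmri-methods.Rmd` documents the simulation model and
its assumptions, every analysis stage, the tunable parameters with their
defaults and rationale, numerical choices, and known limitations.
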