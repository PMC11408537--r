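---
title: "Microstate analysis of MEG and EEG recordings: models, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Microstate analysis of MEG and EEG recordings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(megstates)
```

## The model

Multichannel M/EEG activity can be described as a sequence of
*microstates*: periods of 50-150 ms during which the spatial
distribution of the signal across sensors (the topography) stays
quasi-stable before switching abruptly to another configuration. The
pipeline in this package has four stages:

1. **Topography sampling.** Topographies are extracted at peaks of the
   global field power (GFP), the frames with the highest
   signal-to-noise ratio. For signed, average-referenced EEG the GFP is
   the spatial standard deviation across channels; for combined planar
   gradiometer MEG data, which are nonnegative and reference-free, it
   is the spatial root-mean-square without mean subtraction.

2. **Template identification.** The peak topographies are clustered by
   a modified k-means that is blind to amplitude (all maps are
   unit-normalised) and, in EEG mode, to polarity. Assignment uses the
   mode-specific spatial similarity: absolute Pearson correlation for
   EEG, uncentered cosine for MEG. Template updates are the first
   principal eigenvector of the assigned maps' scatter in EEG mode (the
   polarity-invariant optimum) and the normalised mean with a
   nonnegativity clamp in MEG mode. The number of clusters is chosen by
   a *meta-criterion*: six cluster-validity indices (Gamma, silhouette,
   Davies-Bouldin, point-biserial, Dunn, Krzanowski-Lai) are evaluated
   over a grid of k, min-max normalised, and the median of the
   arg-maxima (including the arg-max of the median curve) is taken.
   Identification is two-level: per-subject clustering first, then
   clustering of the pooled individual templates.

3. **Back-fitting.** The selected templates are competitively fitted to
   every frame of a recording: each frame takes the label of its most
   similar template, unless the best similarity falls below the 0.50
   floor, in which case it stays unlabeled. Labels are then smoothed by
   an iterative Besag-style relabeling that trades the data term
   `1 - sim^2` against a window-occupancy bonus
   `lambda / (2 b) * N_m(t)` with half-window `b = 3` frames and
   `lambda = 10`.

4. **Statistics.** Temporal metrics (coverage, mean duration,
   occurrence rate, global explained variance) feed paired t contrasts
   with Bonferroni correction (`0.05 / 6` per state for six states);
   parcel-level source series and cross-modal co-occurrence are tested
   against *segment-preserving permutation nulls* that shuffle the
   order of label runs while conserving every run's duration, with
   thresholds `|z| >= 3.6` (parcels, Bonferroni-style for a 34 x 6
   grid) and mean `z > 3` across subjects (co-occurrence);
   alpha-band involvement is quantified by the most prominent negative
   dip in the 8-12 Hz power difference between eyes-open and
   eyes-closed rest, correlated with coverage changes via Kendall's
   tau-b; and event-locked effects use detection-rate curves whose
   deviant-minus-standard window mean (150-300 ms) forms the
   microstate mismatch-negativity statistic.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| band | 1-30 | Hz | microstate band; 50 Hz notch removes line noise |
| target rate | 250 | Hz | 4 ms frames, ample for 50-150 ms states |
| artifact epoch | 2 | s | rejection granularity |
| k grid | 2-12 | - | brackets the plausible number of states |
| restarts / tol | 20 / 1e-6 | - | k-means is non-convex; see below |
| similarity floor | 0.50 | - | leaves ambiguous frames unlabeled |
| smoothing | b = 3, lambda = 10 | frames, - | suppresses single-frame blips |
| permutations | 1000 / 10000 | - | parcel / co-occurrence nulls |
| z thresholds | 3.6 / 3.0 | - | grid-corrected / group-mean criteria |
| per-test alpha | 0.05/6, 0.05/204 | - | stored as exact fractions |

The restart default is a compromise: on well-separated synthetic data
12-20 restarts already recover the global optimum in almost every run,
while occasional runs at fewer restarts land in merge/split local
optima. `n_restarts` is exposed everywhere and can be raised for noisy
real data.

## What the synthetic generator emulates - and what it does not

The generator produces piecewise quasi-stable topographic states:
run durations uniform on 50-150 ms, state transitions without immediate
repetition, an amplitude envelope that is a rectified 10 Hz sinusoid
(the alpha band dominates resting M/EEG power, and rectification gives
the GFP a realistic peak cadence of ~20 peaks/s), Gaussian sensor
noise at a configurable SNR, per-run polarity flips in EEG mode
(microstate analysis must be polarity-blind, so the generator exercises
that blindness), and half-normal noise in MEG mode so combined-gradient
nonnegativity is preserved. Condition effects are built in the same
way the analyses expect them: prevalence re-weighting between
conditions, a deviant-locked boost of one state inside the 150-300 ms
deviance-detection window, and parcel series with state-locked offsets.

Two design details deserve explanation:

* **Dwell-time law.** Only the 50-150 ms range of plausible dwell
  times is well established; the empirical distribution of real data is
  not reproduced here, so the generator uses the maximum-entropy choice
  (uniform on the range, clamped to whole frames inside it) and makes
  it configurable.
* **Coverage targets.** Forbidding immediate self-transitions skews
  the stationary distribution of a naive state sampler toward
  `w (1 - w)`. The generator inverts this by a fixed-point adjustment
  of the sampling weights, so the empirical frame coverage converges to
  the requested `coverage_weights` (verified at 600 s within +-0.03).
  Extremely skewed weight vectors (one state above ~2/3) cannot be
  represented exactly under the no-repeat constraint.

What the generator does **not** emulate: 1/f spectral structure,
spatially correlated sensor noise, ocular/cardiac artifacts, volume
conduction or any forward model, head movement, and realistic
306-channel Elekta geometry (layouts are quasi-uniform hemispherical
lattices). Passing tests therefore demonstrate the *algorithmic*
correctness and statistical calibration of every stage under the
model's own assumptions - not that real MEG will yield the same
numbers.

## Numerical choices

* **Explained variance in clustering** is `1 - mean(d)` with the
  mode-specific dissimilarity `d = 1 - sim^2` (EEG) or `1 - sim` (MEG),
  the same `d` the validity criteria use. With these pairings both
  template-update rules provably do not decrease the objective, so the
  iteration's explained variance is monotone (a property the test
  suite asserts per iteration).
* **Ties** are broken deterministically: equal-similarity assignment
  goes to the lowest template index; an even candidate set in the
  meta-criterion takes the lower middle value; among GFP peaks closer
  than the separation limit the larger (then earlier) peak survives.
* **Degenerate inputs** are flagged, not fatal, wherever a statistic
  can legitimately collapse: zero permutation SD yields an undefined-z
  flag, singleton clusters yield NaN criteria, a flat difference
  spectrum yields a zero index with a `no-negative-excursion` flag.
  Hard errors are reserved for contract violations (mismatched shapes,
  empty channel lists, all-tied correlation inputs).
* **Criteria tractability.** The validity indices need the full
  pairwise distance matrix, so they are evaluated on at most 2000
  seeded-subsampled peak maps, with Gamma and point-biserial further
  capped at 50,000 pairs; clustering itself always uses all peaks.
* **Filtering** is zero-phase (forward-backward Butterworth; order 2
  band-stop and high-pass, order 4 low-pass). Resampling is integer
  decimation with the 30 Hz low-pass as anti-alias filter, which
  covers the 1000 -> 250 Hz use case exactly.
* **Artifact rejection** uses a transparent z-value criterion
  (per-channel z-scores, channel-summed absolute maximum per epoch)
  rather than any external tool's proprietary statistic; equivalence
  with such tools is not claimed.
* **Smoothing** freezes sub-threshold frames: the similarity floor is
  applied first and smoothing never labels a frame the floor rejected.
  This is the conservative reading of applying the floor and smoothing
  jointly. No minimum-duration segment rejection is applied.
* **MMN direction.** The mismatch peak is measured on the
  standard-minus-deviant difference of baseline-z-scored, rectified
  epoch averages by default, with `direction = "deviant-standard"`
  available since the classical mismatch negativity is defined the
  other way; the lateralization score is right minus left in either
  convention.
* **Co-occurrence nulls** permute the MEG segmentation and hold EEG
  fixed; per-subject z uses the permutation sample mean and SD (not a
  binomial approximation), and the group decision averages subject z
  grids. Benjamini-Hochberg is the FDR method for the GEV
  correlations.

## Problem sizes used in validation

The test suite and the acceptance script validate at sizes a single
CPU handles in minutes while preserving the statistical structure:
map-recovery and meta-criterion studies use K = 6 states, 64 channels,
240 s at 250 Hz and SNR 10 over 20 seeded replicates; null-calibration
studies pool 34-parcel x 6-state grids over 120 s segmentations with
1000 permutations per seed, and 10-20 simulated subjects with 500
permutations each for the cross-modal null. Unit tests run on 8-32
channel layouts and seconds-long recordings.

## Known limitations

* The meta-criterion implements its published one-sentence description
  (median of criterion arg-maxima including the median curve); other
  toolchains may aggregate their indices differently, and no
  equivalence with any specific implementation is claimed.
* MEG-mode nonnegative noise adds a small positive offset to every
  topography (a noise floor); at SNR 10 its effect on recovered
  templates is below half a percent of similarity but it is not
  removable without violating nonnegativity.
* Parcel statistics use unweighted means over labeled frames;
  correlation-weighted averaging (sometimes used at vertex level) is
  out of scope.
* BrainVision support covers the binary multiplexed IEEE-float-32 and
  vectorized ASCII dialects (the ones the package writes), not INT_16
  data or segmented files.

## A minimal worked example

```{r example, eval = FALSE}
lay  <- make_layout(32, seed = 1)
maps <- make_topographies(4, lay, mode = "meg", seed = 2)
sim  <- simulate_resting(lay, maps, duration_s = 60, fs = 250,
                         snr = 10, seed = 3)

peaks <- find_gfp_peaks(gfp(sim$recording))
sel   <- select_microstates(t(sim$recording$data[, peaks]), "meg",
                            k_grid = 2:8, seed = 4)
sel$k_opt                                   # 4

seg <- smooth_labels(backfit(sim$recording, sel$microstates))
temporal_metrics(seg)
match_maps(maps, sel$microstates, "meg")$mean_sim
```
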