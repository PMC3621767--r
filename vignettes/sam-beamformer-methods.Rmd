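---
title: "Beamformer source analysis of oddball MEG: models, parameters, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Beamformer source analysis of oddball MEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(megsam)
```

`megsam` localizes the cortical generators of the auditory mismatch
response from MEG oddball experiments with a scalar (optimal-orientation)
LCMV beamformer — the approach known as Synthetic Aperture Magnetometry
(SAM) — combined with nonparametric maximal-statistic permutation
inference and virtual-sensor time-course extraction.  Because raw
recordings from such studies are rarely shareable, the package ships a
synthetic oddball-MEG generator that emulates the full acquisition chain,
so every analysis stage can be validated by recovering known dipoles.
This vignette documents the models, their assumptions, the tunable
parameters, and what the validation does and does not show.

## The experimental design being modeled

A short melodic sequence — six tones of 300 ms, 1800 ms in total —
repeats every 2700 ms (900 ms silent gap).  Most repetitions are
*standards*; in 20% of trials (80 of 400 per run, two runs) the final
tone is altered (*deviant*).  Rare deviants in a repetitive stream evoke
the mismatch negativity (MMN), an event-related field peaking roughly
100–250 ms after the deviating event, generated in superior temporal and
inferior frontal cortex.

`generate_oddball_events()` lays out this schedule deterministically per
seed.  Deviant positions are drawn uniformly among the arrangements in
which the first trial is a standard and no deviant follows a deviant
(rejection-free sampling over the "gaps after standards", which is in
bijection with the admissible arrangements).  Non-adjacency matters
downstream: the contrast pairs each deviant with its *immediately
preceding* standard, so the analyzed standards number exactly the
deviants — 80 per run, 320 analyzed epochs across two runs — which keeps
the background brain state of the two covariance states as similar as
possible.

## Forward model

The head is a homogeneous conducting sphere (default radius 9 cm,
origin at its center; x right, y anterior, z superior; outputs in mm in
this frame).  For magnetometers outside the sphere the field of an
internal current dipole has the Sarvas closed form, independent of the
radial conductivity profile, and radial dipoles are silent — so each
source has only two effective (tangential) degrees of freedom, and
`build_leadfield()` stores a channels × 3 gain of rank 2 per grid point.
Per-channel sphere centers (the local-spheres idea) are supported as
data, but no fitting to anatomy is implemented: synthetic subjects share
one head by construction, which also replaces any spatial normalization
step with the identity.

The default array is a synthetic 275-channel helmet: point magnetometers
on a golden-angle spiral over a spherical cap (radius 12 cm, opening
115°), radially oriented.  Real axial-gradiometer geometry is not
reproduced; the analysis mathematics are geometry-agnostic.  Channel
regions are positional conventions — frontal (y > 4 cm), left/right
temporal (|x| > 5 cm, y ≤ 4 cm), other — and partition the array for the
sensor-subset analyses.

Source grids are axis-aligned cubes clipped to the sphere with a margin
of one spacing from the surface *and from the center* (the center is
magnetically degenerate).  Production spacing is 3 mm; validation runs
use 10–14 mm so that a full cohort fits in minutes.

## Synthetic recordings

`simulate_recording()` sums three components and applies the acquisition
low-pass (150 Hz, 4th-order Butterworth, zero phase; sampling 600 Hz):

* **Deterministic sources** (`source_spec`): fixed location and
  tangential orientation; the moment follows a Hanning envelope (default
  width 120 ms) after each trigger.  `evoked` sources fire at every tone
  onset; `deviance` sources fire only at the final tone of deviant
  trials, peaking at a configurable latency (defaults: right STG 150 ms,
  right IFC 140 ms — the IFC-earlier ordering gives the latency tests a
  known ground truth).  Each trigger's amplitude is jittered
  (multiplicative, sd 0.2) to model trial-to-trial variability; the
  `correlated_bilateral` flag shares these gains across deviance
  sources, producing *exactly* zero-lag-correlated bilateral activity.
* **Background brain noise**: 200 random tangential dipoles inside 80%
  of the sphere radius with white Gaussian moments (sd 10 nA·m each),
  giving spatially correlated noise with a realistic dipolar covariance
  structure.
* **Sensor noise**: white, 20 fT per sample per channel.

Amplitude calibration: the default deviance moment is 60 nA·m, which
puts the deviance response near −10 dB relative to the ongoing activity
integrated over a whole 3.6 s epoch (the burst occupies only ~120 ms, so
the within-window SNR is ≈ +4 dB).  This is the regime in which ~10–80
trials of averaging/covariance estimation are needed for stable maps —
and in which the beamformer's correlated-source cancellation, the
phenomenon motivating hemisphere-split analyses, actually engages.  At
substantially lower window SNR the beamformer degenerates to a matched
filter: single sources still localize, but correlated pairs are *not*
suppressed, and no trial count rescues this (covariance SNR does not
grow with trials).  This interaction is easy to miss and is the single
most important property of the fixture design.

What the generator does **not** emulate: ongoing rhythms (alpha etc.),
eye/muscle physics (artifacts are generic frontal-weighted 0.5 s
deflections), head movement, gradiometer coil geometry, anatomical
variability.  Passing tests therefore demonstrate correctness of the
analysis chain under known physics, not performance on any particular
real dataset.

## Preprocessing

Epochs of 3.6 s (0.2 s pre-stimulus) are cut at sequence onsets; the
final tone then sits at +1.5 s, and all analysis windows are specified
relative to it.  The analysis band-pass is 1–30 Hz.  Filtering is
zero-phase: the spectrum is multiplied by |H(e^{iω})|² of the 4th-order
Butterworth — the exact frequency-domain counterpart of
forward–backward filtering — with odd-reflection padding; continuous
recordings are filtered before cutting so filter edges stay out of the
epochs.  Artifact rejection removes every epoch whose field exceeds 3 pT
in any channel (peak absolute amplitude by default; a peak-to-peak
criterion is available).  No further baseline correction is applied
beyond the filter's DC removal.

## The SAM pseudo-T statistic

For each grid point, sensor subset, and analysis window (defaults
100–200 ms and 200–300 ms post-deviant):

1. **Covariances**: `C_a` from the deviant-trial windows, `C_c` from the
   *same interval* of the paired standard trials; each is the average
   over trials of the window sample covariance with the per-trial window
   mean removed.  Weights are computed from the pooled covariance
   `C = (C_a + C_c)/2` so one filter serves both states (keeping
   `a² − c²` unbiased under the null); pooling is the standard
   dual-state SAM practice.
2. **Regularization**: `C_reg = C + λ·tr(C)/N·I`, λ = 0.05 by default
   (0 allowed).  Band-limited 100 ms windows over tens of trials give
   effectively rank-deficient covariances; loading is required for a
   stable inverse.
3. **Orientation**: the tangential direction maximizing output power
   over projected noise power — the leading generalized eigenvector of
   `(GᵀC⁻¹G, GᵀC⁻²G)` restricted to the gain's effective column space.
   Deterministic, and equivalent at the optimum to the classical
   nonlinear orientation search.
4. **Weights**: `w = C_reg⁻¹h / (hᵀC_reg⁻¹h)`, `h = G·orientation`
   (unit gain at the target).
5. **Pseudo-T**: `(a² − c²)/n²` with `a² = wᵀC_a w`, `c² = wᵀC_c w`, and
   `n² = σ²_min · wᵀw`, where σ²_min is the smallest singular value of
   the pooled covariance — the SVD estimate of the sensor-noise floor,
   "spuriously mapped" to the source by the weights.  Inside the map
   computation σ²_min is taken from the *loaded* pooled covariance:
   without loading, the smallest singular value of a rank-deficient
   band-limited covariance is numerical noise and the statistic's scale
   becomes meaningless.  With λ = 0 this reduces to the plain SVD
   estimate, which is what the standalone `noise_power()` operation
   implements and what the hand-computed oracle tests check.

Pseudo-T values are *not* Student t statistics; they are noise-normalized
power contrasts, invariant to global gain rescaling, and exactly zero
when the active and control inputs coincide.

Correlated sources: a beamformer assumes one source per location, so
bilateral generators with (near) zero-lag correlated time courses
partially cancel — whole-head maps lose the true peaks (a weak midline
"phantom" pattern can remain).  Processing left-temporal, right-temporal
and frontal sensor subsets separately restores per-hemisphere recovery
because each subset barely sees the contralateral source.  The package
reproduces both effects quantitatively (suppression to < 50%, split
recovery within one grid spacing) in its acceptance checks.

## Group inference

Subject maps (averaged across runs) are averaged voxelwise; thresholds
come from the maximal-statistic permutation test: under the null,
deviant/standard labels are exchangeable and relabeling negates each
subject's contrast, so the null is built from random sign-flips of the
subject maps; each permutation's statistic is the image-wide maximum of
the flipped mean, which controls family-wise error across voxels by
construction.  The threshold is the `ceil((1−α)(n_perm+1))`-th order
statistic of {observed, permuted} maxima; α = 0.05; the default
`n_perm = 4999` is a package choice (tests use 999).  With `n_perm = 2^n − 1` the full flip set is
enumerated and the result is seed-free.  The test is one-sided on
positive contrasts (activations) by default, two-sided optionally; a
slow subject-level relabel-and-recompute hook exists for validation.
Multiple windows/subsets are thresholded independently, without
cross-analysis correction.

Peaks are local maxima above threshold with a 20 mm suppression radius,
reported in head-frame mm.

## Virtual channels and latency ordering

`location_weights()` computes weights at any coordinate from the pooled
covariance of the early (100–200 ms) window — the convention for
time-course extraction — and `extract_virtual_channel()` projects every
epoch through them.  Per subject and condition the activity is
summarized as the RMS across trials at each sample (the source
description is ambiguous between this and the absolute evoked trace;
`method = "evoked"` selects the alternative), averaged across subjects,
and differenced (deviant − standard).  The peak of the difference within
0–300 ms post-deviant estimates the mismatch latency; with the default
fixture the IFC peak precedes the STG peak by 10 ms.

## Numerical choices and degenerate inputs

* Orientation sign is fixed (first nonzero component positive);
  orientation in rank-1 gain cases falls back to the single direction.
* Rank decisions use a 1e−8 relative singular-value cutoff.
* Grid points with zero gain (none, given the center exclusion) would map
  to 0.
* `reject_artifacts` refuses to silently return an empty epoch set;
  empty sensor regions and empty windows are errors, not empty results.
* Floating-point reproducibility is promised within one platform/BLAS;
  across platforms agreement is ~1e−10 relative, not bit-exact.

## Validation scales

The acceptance checks run at desk scale, chosen once: localization uses
8 subjects × 12 deviant/standard pairs on a 10 mm grid; correlated
suppression 2+2 subjects × 40 pairs (alternating oddball — the criterion
tests covariance physics, not deviant probability); the FWER check
builds a pool of 24 genuine source-free subjects (100-channel array,
14 mm grid, 8 pairs) and assembles 200 null datasets of 8 subjects by
resampling with independent random signs — valid because the null
contrast is symmetric and the sign-flip test is exact conditional on any
fixed map set; latency recovery uses 8 subjects × 20 pairs.  The
full-size design (320+80 × 2 runs, 275 channels, 3 mm grid) runs through
the same code via `run_pipeline()` but takes hours on one CPU rather
than minutes.

## Known limitations

* Single-sphere conductor and point magnetometers: adequate for testing
  the analysis chain, not a substitute for individual head modeling.
* The pseudo-T scale depends on the regularization through n²; compare
  values only within a fixed configuration.
* Hemisphere-split analyses cut the midline: medially-generated activity
  is better assessed with the frontal subset, and deep midline activity
  remains hard for any beamformer.
* The synthetic noise model has no 1/f or rhythmic structure, so
  real-data SNR at matched amplitudes will differ; fixture amplitudes
  are calibrated for testability, not biophysical exactness.
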