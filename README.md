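# megsam

Source localization of auditory mismatch responses from MEG oddball
experiments, for electrophysiologists and methods developers who want a
fully inspectable, testable implementation of the classic SAM-style
analysis chain:

* **Scalar LCMV beamformer (SAM) with pseudo-T contrasts.** For a grid
  point with gain `G`, pooled window covariance `C` and optimal tangential
  orientation `u` (the leading generalized eigenvector of
  `(GᵀC⁻¹G, GᵀC⁻²G)`), the spatial filter is `w = C⁻¹h / (hᵀC⁻¹h)` with
  `h = Gu`, and the statistic contrasts an active (deviant) window against
  a control (paired preceding-standard) window:

  `pseudo-T = (a² − c²) / n²`, `a² = wᵀC_a w`, `c² = wᵀC_c w`,
  `n² = σ²_min(C) · wᵀw`

  where `σ²_min` is the SVD estimate of the sensor-noise floor.
* **Maximal-statistic permutation inference** (sign-flips of subject
  contrast maps; image-wide maximum; family-wise-error control by
  construction) with peak tables in head-frame mm.
* **Virtual channels**: beamformer weights applied to every epoch to
  extract source time courses, RMS difference waveforms, and mismatch peak
  latencies.
* **An analytic spherical forward model** (Sarvas solution; radial
  dipoles silent) and **a synthetic oddball-MEG generator** — 275-channel
  helmet, 600 Hz / 150 Hz acquisition, six-tone 1800 ms melodies at
  2700 ms SOA, 320 standards + 80 deviants per run, deviance-specific
  STG/IFC sources, correlated brain noise, sensor noise, >3 pT
  artifacts — so the whole chain is verifiable by dipole recovery.

## Worked example

A reduced single-subject session, end to end:

```r
library(megsam)

head  <- head_model()                       # 9 cm conducting sphere
array <- make_sensor_array()                # synthetic 275-channel helmet
spec  <- trial_spec(n_standard = 21, n_deviant = 20, n_runs = 1)
ev    <- generate_oddball_events(spec, seed = 1)
pairs <- select_analysis_trials(ev)         # deviant + preceding standard
nrow(pairs)
#> [1] 20

src <- default_sources()                    # bilateral STG evoked + rSTG/rIFC deviance
rec <- simulate_recording(sim_config(sources = list(src$rSTG_deviance), seed = 2),
                          ev, head, array)
rec <- bandpass_filter(rec, 1, 30)
ep  <- reject_artifacts(extract_epochs(rec, ev))   # 3.6 s epochs, 3 pT rejection
ep
#> Epoch set: 41 trials (20 deviant) x 275 channels x 2160 samples @ 600 Hz

grid <- make_source_grid(head, spacing_mm = 10)
lf   <- build_leadfield(grid, array, head)
map  <- pseudo_t_map(pairs, ep, lf, window_pair(c(0.100, 0.200)))
map
#> Pseudo-T map: 2102 grid points, window [0.1, 0.2] s post-deviant, 275 channels, 20 pairs
#>   range [-2.474, 15.416], peak at (50, -20, 40) mm
map_peak_location(map)                      # simulated source sat at (50, -20, 40)
#>   x   y   z 
#>  50 -20  40
```

The peak lands on the simulated dipole.  With several subjects,
`permutation_threshold()` + `report_peaks()` give the thresholded group
map, and `location_weights()` + `extract_virtual_channel()` +
`rms_difference_waveform()` return the mismatch time course and its peak
latency at any coordinate.  `run_pipeline()` (or
`inst/scripts/run_pipeline.R` from a shell) chains all stages for a whole
simulated cohort and writes NIfTI maps, TSV peak/waveform/event tables,
a log, and a manifest.

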