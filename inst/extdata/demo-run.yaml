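# Reduced demo configuration: 2 simulated subjects, one short run each,
# coarse 20 mm grid, one analysis window.  Finishes in a few minutes.
#   Rscript inst/scripts/run_pipeline.R --config inst/extdata/demo-run.yaml --out demo-out
n_subjects: 2
seed: 7
array:
  n_channels: 60
paradigm:
  n_standard: 11
  n_deviant: 10
  n_runs: 1
beamformer:
  windows:
  - [0.100, 0.200]
  grid_spacing_mm: 20
  subsets: [left-temporal, right-temporal]
group:
  n_perm: 99
virtual:
  n_locations: 1
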