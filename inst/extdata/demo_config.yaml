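# Minimal end-to-end demo configuration for `run_pipeline()` /
# `roscope.R run`. Twelve small cells (two per condition x treatment group),
# two training epochs; runs in well under a minute on one CPU.
seed: 1
task: treatment
out_size: 256
scene:
  image_size_px: 96
  n_slices: 3
  pixel_size_um: 0.5
  cell_radius_um: [12, 18]
design:
  n_per_group: 2
split:
  fractions: [0.72, 0.08, 0.20]
  grouping: by_slice
train:
  epochs: 2
  batch_size: 8
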