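# Example run configuration for the bcsfusion command-line pipeline.
# Paths are relative to where you run the command.
seed: 1
paths:
  data: bcs_data
  out: bcs_out
scene:
  n_cows: 40
  sensor: [106, 128]
  noise_sd: 5
  frames_per_cow: [5, 7]
preprocess:
  ANGLED: {distance_threshold: 3000, crop: [33, 47, 32, 32], binarize_threshold: 2700, gradient_cap: 250}
  REAR:   {distance_threshold: 2900, crop: [37, 47, 32, 32], binarize_threshold: 2600, gradient_cap: 250}
  TOP:    {distance_threshold: 2600, crop: [38, 40, 32, 32], binarize_threshold: 2200, gradient_cap: 250}
split:
  test_fraction: 0.3
  cap: 7
  stratify: true
model:
  fusion: LATE
  cameras: [ANGLED, REAR, TOP]
train:
  learning_rate: 0.001
  epochs: 25
  batch_size: 32
  class_weighting: true
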