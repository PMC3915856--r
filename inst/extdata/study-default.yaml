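# Default study configuration: the calibrated study conditions.
schema_version: 1
seed: 1
markers: [caspase3, Notch1]
pairs: [Notch1-Delta1]
calibration:
  replicate_noise_cv: 0.05
  rats_per_timepoint: 4
  n_hemo_rats: 6
  poisson_counts: true
  merge_fraction: 0.1
pla:
  threshold: 100
  min_size: 2
  max_size: 50
  median_size: 10
stats:
  alpha: 0.05
  welch: false
  holm: false
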