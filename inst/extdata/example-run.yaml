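# Minutes-scale demonstration pipeline (synthetic data, test-tiny models).
seed: 1
out_dir: tailkd-run
data:
  source: synthetic
  divisor: 16
  side: 48
  noise_sd: 8
augment:
  enabled: true
  small_class_threshold: 7
  floor_target: 6
groups:
  head_min: 13
  balance_min: 4
train:
  epochs: 5
  batch_size: 32
  expert_variant: test-tiny
  student_variant: test-tiny
distill:
  temperature: 4
  alpha: 0.5
eval:
  batch_size: 64
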