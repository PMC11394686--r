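# Demonstration study: 2 groups x 10 subjects, 5 regions (M1, CPu, STN,
# SNc, PPN), one 5-minute resting and one 5-minute walking phase at 1000 Hz,
# pink-noise background with the bundled walk-state band effects.
seed: 1
synthetic:
  n_per_group: 10
  fs: 1000
  state_duration_s: 300
  noise_exponent: 1.0
  noise_scale: 12
  subject_sd: 0.2
  demo_effects: true
filter_low: 0.5
filter_high: 80
artifact_k: 6
segment_s: 10
epoch_length_s: 1
sphericity_alpha: 0.05
include_behavior: true
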