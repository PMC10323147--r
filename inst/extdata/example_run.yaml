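# Example run configuration: the built-in two-trait, two-cue model with a
# related population and overlapping generations.
env:
  n_gen: 60
  ramp_start: 10
  cue_ramp_slopes: [0.05, 0.015]
n: 100
rel: band
ft: 0.5
methods: [robertson, grad]
seed: 1
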