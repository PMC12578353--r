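network:
  n_units: 240
  sparseness: 0.2
  conn_mean: 49.881
  conn_sd: 4.988
  gain: 0.1
  tau: 0.02
  dt: 0.001
  seed: ~
noise:
  mean: 20.0
  sd: 11.5
  dc_offset: 0.0
  filter: ~
  seed: ~
proxy:
  alpha: 0.01
  n_samples: 2
  seed: ~
bands:
  slow:
  - 0.01
  - 0.1
  fast:
  - 1.0
  - 10.0
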