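schema_version: 1
units: m
seed: 1
sim:
  dt: 0.0166666666666667
  iterations: 10
  use_ddc: true
  gravity: [0.0, -9.81, 0.0]
  friction_k: 0.5
  collision_enabled: true
rods:
- type: straight
  total_length: 0.05
  n_elements: 20
  K_b: 0.05
  K_t: 0.25
  d_v: 0.1
  d_a: 0.1
  pin: [1]
run:
  duration: 1.0
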