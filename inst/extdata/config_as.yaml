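# Example run configuration: severe aortic stenosis at 75 bpm.
T: 0.8
params:
  valves.aortic.A_eff_max: 0.75
  lv.E_es: 3.0
solver:
  beats: 15
  dt: 0.001
ea:
  pop: 50
  generations: 60
  stall: 15
morris:
  r: 10
  range_frac: 0.3
cohort:
  "n": 12
  jitter: 0.15
  K: 18
  n_moderate: 1
seed: 1
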