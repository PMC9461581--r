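# Example socforage configuration: two pulsatile-coupled foragers.
mode: pulsatile
noise_scale: 1.0
env:
  rho: 2.0
  tau: 5.0
  alpha: 1.0
  travel_time: 5.0
agents:
- theta: -1.0
  kappa: 0.5
- theta: -1.0
  kappa: 0.5
settings:
  dt: 0.01
  t_max: 150.0
  n_trials: 100
  seed: 7
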