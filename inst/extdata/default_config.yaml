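# Selected parameter values of the age-structured role-reversal model
# (see ?model_parameters for meanings and units).
parameters:
  tau_star: 1.0
  g: 0.2
  nu: 100.0
  r: 0.4
  a: 0.01
  k: 0.3
  b: 0.8
  s: 0.2
  zeta: 10.0
  mu_M: 1.0
  rho: 5.0
  d_p: 0.4
  b_p: 0.05
  b_ep: 0.1
  d_ep: 0.1
  L: 30.0
  x_hat: 20.0
  y1_hat: 10.0
  variant: baseline
solver:
  h: 0.005
  T_max: 500.0
  blowup_threshold: 1000.0
  record_every: 0.25
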