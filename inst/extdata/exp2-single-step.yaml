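# single-step full-range transition 0.0697 -> 0.6000 1/day using one
# high-dilution observer whose asymmetric target area covers the whole
# admissible range (the nominal 0.65 1/day is a package-chosen synthetic
# stand-in for the high-dilution design point of this scenario)
params:
  delta: 0.15151515151515152
  mu_m: 1.2
  K: 4.95
  s_in: 9.0
bank_U: [0.65]
a: 3.5
zeta_oa: 0.5
chi_oa: 0.5
chi_ob: 0.001
from: 0.0697
to: 0.6000
identify: true
noise_amplitude: 0.0
ident_horizon: 400.0
ident_step: 0.01
ident_window: [200.0, 400.0]
timing_factor: 1.1
step: 0.01
seed: 1
symmetric: false
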