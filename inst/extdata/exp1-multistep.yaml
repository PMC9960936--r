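# four-step transition 0.2134 -> 0.6000 1/day through hand-picked
# intermediate operating points, one identified observer per point
params:
  delta: 0.15151515151515152
  mu_m: 1.2
  K: 4.95
  s_in: 9.0
bank_U: [0.2134, 0.2579, 0.2826, 0.4500, 0.6000]
a: 3.5
zeta_oa: 0.5
chi_oa: 0.5
chi_ob: 0.001
from: 0.2134
to: 0.6000
intermediates: [0.2579, 0.2826, 0.4500]
identify: true
noise_amplitude: 0.0
ident_horizon: 400.0
ident_step: 0.01
ident_window: [200.0, 400.0]
timing_factor: 1.1
step: 0.01
seed: 1
symmetric: true
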