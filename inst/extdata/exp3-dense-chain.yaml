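# seven-step low-dilution chain 0.0608 -> 0.5149 1/day over a dense set of
# consecutive operating points with overlapping symmetric target areas
params:
  delta: 0.15151515151515152
  mu_m: 1.2
  K: 4.95
  s_in: 9.0
bank_U: [0.0608, 0.0714, 0.0905, 0.1193, 0.1595, 0.2215, 0.3059, 0.5149]
a: 3.5
zeta_oa: 0.5
chi_oa: 0.5
chi_ob: 0.001
from: 0.0608
to: 0.5149
intermediates: [0.0714, 0.0905, 0.1193, 0.1595, 0.2215, 0.3059]
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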