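# benchmark Monod chemostat constants
delta: 0.15151515151515152
mu_m: 1.2
K: 4.95
s_in: 9.0
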