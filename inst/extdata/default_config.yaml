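a0: 0.3
d0: 0.4
k0: 0.05
m0: 0.002
E0: 0.0002
F: 10.0
c_max: 60.0
N0: 500.0
t_max: 50.0
N_cap: 50000.0
seed: 42
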