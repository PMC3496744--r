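# Breakable-filament reference configuration. Chosen so that the
# quasi-stationary mean polymer size sqrt(n_ends*k_p*m0/k_f) ~ 160
# (continuum small parameter eps ~ 0.006), the regime where the PDE
# limit is accurate. Units: k_p 1/(uM h), k_f 1/h, k_n 1/(uM h), m0 uM.
model: knowles
k_p: 5
k_f: 4.0e-3
k_n: 1.0e-5
m0: 10
n_c: 2
n_ends: 2
t_max: 30
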