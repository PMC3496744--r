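# Step-rate growth reference configuration: slow polymerization below
# the step at n_c, fast above; per-bond fragmentation; nucleus loss by
# depolymerization only. Units: k_low/k_high 1/(uM h), k_d and k_f 1/h,
# m0 uM.
model: xue
i0: 2
n_c: 10
k_low: 0.05
k_high: 2
k_d: 0.05
k_n: 1.0e-4
frag_kind: uniform
k_f: 5.0e-3
m0: 20
t_max: 30
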