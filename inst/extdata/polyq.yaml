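# PolyQ reference configuration: activation scheme W -> V <-> V* with a
# monomeric-conformer nucleus (i0 = 1) and tent-shaped elongation rate.
# Rates in 1/h (tau_max in 1/(uM h)), concentrations in uM, sizes in
# monomer units. Order-of-magnitude realistic values chosen as the
# package's reference conditions (see the methods vignette); x2 and x3
# are fixed by convention, not fitted.
model: polyq
k_act: 0.15
k_plus: 0.4
k_minus: 0.2
k_on: 0.02
k_off: 2.0
i0: 1
tau_max: 0.3
x1: 5
x2: 15
x3: 30
w0: 40
# three-concentration design used by the fitting demos
w0_list: [20, 40, 60]
t_max: 48
n_points: 50
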