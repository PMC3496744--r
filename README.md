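# amykin

Kinetic modelling of amyloid fibril assembly: simulation and
least-squares estimation for nucleated protein polymerization, built
around a matched pair of engines — the truncated discrete
size-by-size ODE system and its continuum (size-structured PDE) limit
with a quasi-steady-state nucleation boundary.

**Who it is for.** Biophysicists and modellers analysing aggregation
kinetics (ThT fluorescence, static light scattering) of amyloid-forming
proteins — polyglutamine, breakable filaments, step-rate growth models —
who need fast, mass-conservative simulations of
nucleation/elongation/fragmentation/coalescence schemes and a
reproducible fitting protocol for growth curves.

## The model

Monomer pools (precursor W, native V, aggregation-prone conformer V\*)
couple to polymers of size *i* ≥ *i₀*:

* activation W → V (`k_act`), exchange V ⇌ V\* (`k_plus`, `k_minus`);
* nucleation *i₀* V\* → C(i₀) at `k_on (V*)^n_nuc`, dissociation `k_off`;
* elongation/depolymerization by single monomers at size-dependent
  rates τ(i), d(i);
* binary fragmentation with per-bond rate `B(i) = k_f (i−1)` and a
  symmetric daughter distribution; Smoluchowski coalescence κ(x, y);
  degradation γ(i).

For mean sizes ≫ 1 the ladder of ODEs is replaced by a transport
equation for the density u(t, x),

∂ₜu + ∂ₓ[(τ(x)V\* − d(x)) u] = −γ(x)u + (fragmentation) + (coalescence),

with the nucleus slaved to its quasi-steady state
c_QSS = k_on (V\*)^n_nuc / (k_off + τ(x₀)V\*) and the boundary in-flux
τ(x₀)V\* c_QSS. The PDE is solved by a conservative first-order upwind
scheme (CFL-adaptive explicit stepping); the discrete system — solved by
`deSolve::lsoda` or a compiled fixed-step RK4 — serves as its
brute-force oracle.

Three model families ship ready-made: the PolyQ activation scheme with
a monomeric-conformer nucleus, the Knowles-type breakable-filament
model with its exact two-moment reduction, and the Xue-type step-rate
model with a hybrid discrete-below/continuum-above solver.

## Worked example

Simulate the PolyQ reference configuration at three concentrations,
generate noisy synthetic ThT data, fit them back and select the
nucleus size:

```r
library(amykin)

p <- polyq_params()                # reference configuration, i0 = 1
m <- polyq_model(p)
tr <- simulate_polyq(m, times = seq(0, 48, length.out = 50))
tht <- tht_signal(tr)
transition_params(tht)
#> <transition_params> lag = 7.69 h, max slope = 2.035 /h, inflexion at 12.73 h

ds  <- generate_tht_dataset(p, w0_list = c(20, 40, 60),
                            noise_sd = 0.01, seed = 7)
cfg <- fit_config(n_starts = 12, n_refine_starts = 6, max_evals = 800,
                  seed = 42)
fit <- fit_polyq(ds$curves, i0 = 1, config = cfg)
fit
#> <agg_fit> PolyQ fit, i0 = 1 , mode = simultaneous 
#>   global adimensioned L2 error: 0.01317 
#>   parameters:
#>    k_act   k_plus  k_minus     k_on    k_off  tau_max 
#> 0.201500 0.659300 0.009528 0.005352 0.642200 0.174200 

select_nucleus_size(ds$curves, i0_candidates = 1:3, config = cfg)
#> Nucleus-size selection (global adimensioned L2 error):
#>   i0 global_error
#> 1  1   0.01317259
#> 2  2   0.01465763
#> 3  3   0.01839083
#> Selected i0 = 1
```

Reading the output: the fitted curve sits at the 1% noise floor
(global error ≈ 0.013, i.e. about 1% of the plateau in the
adimensioned L2 norm); the individual rates land in the shallow,
nearly noise-degenerate valley that the methods vignette describes
under *Estimation protocol* (the curve constrains rate combinations
much more tightly than single rates — compare the fitted `k_minus`
drifting to zero with compensating shifts elsewhere); and the
selection table recovers the generating nucleus size `i0 = 1`, with
the error growing in the candidate nucleus size.

The Knowles-type three-way comparison (exact discrete system vs PDE
limit vs two-moment reduction) is one call each:

```r
kp  <- knowles_params()            # stationary mean size ~158 monomers
tt  <- seq(0, 30, 0.25)
dm  <- knowles_discrete_model(kp, N_max = 1600)
trd <- integrate_discrete(dm, initial_state(dm, v_star = kp$m0), tt)
g   <- size_grid(2, 1266, 632)
pm  <- knowles_pde_model(kp, g)
trp <- integrate_pde(pm, continuous_state(pm, v_star = kp$m0), tt)
compare_models(trp, trd, "M1")
#> [1] 0.004367462
```

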