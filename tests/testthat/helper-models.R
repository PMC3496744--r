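# Shared fixtures: small model configurations built in code.

traj_moment <- function(tr, order, threshold = 0) {
  observable_series(tr, c("M0", "M1", "M2")[order + 1])$values
}

total_mass <- function(tr) {
  tr$w + tr$v + tr$v_star + traj_moment(tr, 1)
}

# a fully-featured small discrete model exercising every reaction term
random_full_model <- function(frag_kind = "mechanical", coag = TRUE) {
  discrete_model(
    i0 = 2, N_max = 30, k_on = 0.05, k_off = 1,
    tau = rate_piecewise_linear(3, 10, 25, 0.4),
    d = rate_constant(0.1),
    frag = fragmentation_kernel(frag_kind, 0.02),
    coag = if (coag) coalescence_kernel(0.01) else NULL,
    k_plus = 1, k_minus = 0.5, k_act = 0.3)
}

random_state <- function(model, seed = 1) {
  set.seed(seed)
  n <- model$N_max - model$i0 + 1L
  initial_state(model, w = runif(1, 0, 3), v = runif(1, 0, 3),
                v_star = runif(1, 0, 3), c = runif(n, 0, 0.5))
}

state_as_vec <- function(s) c(s$w, s$v, s$v_star, s$c)
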