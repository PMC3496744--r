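test_that("QSS nucleation boundary flux has the right limits", {
  g <- size_grid(2, 60, 29)
  m <- pde_model(g, k_on = 0.3, k_off = 2, tau = rate_constant(0.05),
                 n_nuc = 2)
  expect_equal(nucleation_boundary_flux(0, m)$number_flux, 0)
  m0 <- pde_model(g, k_on = 0.3, k_off = 0, tau = rate_constant(0.05),
                  n_nuc = 2)
  vs <- 3
  expect_equal(nucleation_boundary_flux(vs, m0)$number_flux, 0.3 * vs^2)
  nf <- nucleation_boundary_flux(vs, m)
  expect_equal(nf$c_qss, 0.3 * vs^2 / (2 + 0.05 * vs))
  expect_equal(nf$mass_flux, nf$number_flux * g$centers[1])
})

test_that("QSS nucleus concentration matches the discrete long-time value", {
  # matched parameters: run the discrete oracle into its slaved regime
  dm <- discrete_model(i0 = 2, N_max = 60, k_on = 1e-6, k_off = 0.5,
                       tau = rate_constant(0.05))
  tr <- integrate_discrete(dm, initial_state(dm, v_star = 10),
                           seq(0, 40, 2), method = "lsoda", rtol = 1e-10)
  g <- size_grid(2, 60, 29)
  pm <- pde_model(g, k_on = 1e-6, k_off = 0.5, tau = rate_constant(0.05),
                  n_nuc = 2)
  k <- length(tr$times)
  cq <- nucleation_boundary_flux(tr$v_star[k], pm)$c_qss
  expect_equal(cq, tr$c[k, 1], tolerance = 0.01)
})

test_that("upwind transport translates a profile at the right speed", {
  # constant speed s, no sources: method-of-characteristics oracle.
  # the speed tau * v_star is held constant by a huge monomer reservoir
  # (relative depletion ~ 5e-4 over the run)
  s_speed <- 5
  err_for <- function(n_cells) {
    gg <- size_grid(0, 200, n_cells)
    mm <- pde_model(gg, k_on = 0, k_off = 0,
                    tau = rate_constant(s_speed / 1e6))
    uu0 <- exp(-((gg$centers - 50) / 6)^2)
    tr <- integrate_pde(mm, continuous_state(mm, v_star = 1e6, u = uu0),
                        times = c(0, 10))
    exact <- exp(-((gg$centers - 50 - s_speed * 10) / 6)^2)
    sum(abs(tr$u[2, ] - exact)) * gg$dx
  }
  e1 <- err_for(200); e2 <- err_for(400); e3 <- err_for(800)
  expect_gt(e1 / e2, 1.3)             # roughly first-order in dx
  expect_gt(e2 / e3, 1.3)
})

test_that("pde derivative is zero without transport or kernels", {
  g <- size_grid(2, 50, 24)
  m <- pde_model(g, k_on = 0, k_off = 0)
  st <- continuous_state(m, u = rep(0.1, 24))
  d <- pde_rhs(st, m)
  expect_equal(d$u, rep(0, 24))
  expect_equal(c(d$w, d$v, d$v_star), c(0, 0, 0))
})

test_that("continuum fragmentation operator conserves mass cell-by-cell", {
  g <- size_grid(2, 100, 49)
  for (kind in c("uniform", "mechanical")) {
    m <- pde_model(g, k_on = 0, k_off = 0,
                   frag = fragmentation_kernel(kind, 0.05))
    set.seed(2)
    st <- continuous_state(m, u = runif(49))
    d <- pde_rhs(st, m)
    # d/dt [v* + int x u dx] restricted to the fragmentation operator
    dmass <- d$v_star + sum(g$centers * d$u) * g$dx
    expect_equal(dmass, 0, tolerance = 1e-12)
  }
})

test_that("continuous moments agree with quadrature and binned states", {
  g <- size_grid(2, 50, 24)
  m <- pde_model(g, k_on = 0, k_off = 0)
  st <- continuous_state(m)
  expect_equal(continuous_moment(st, 1), 0)
  u <- rep(0, 24); u[10] <- 3        # indicator cell
  st2 <- continuous_state(m, u = u)
  expect_equal(state_moment(st2, 1), 3 * g$dx * g$centers[10])
  # rebinning a discrete state yields matching moments
  dm <- discrete_model(i0 = 2, N_max = 49, k_on = 0, k_off = 0)
  set.seed(3)
  cc <- runif(48)
  sd <- initial_state(dm, c = cc)
  ub <- as.numeric(tapply(cc, findInterval(seq(2, 49), g$edges,
                                           rightmost.closed = TRUE),
                          sum)) / g$dx
  sc <- continuous_state(m, u = ub)
  expect_equal(state_moment(sc, 1), state_moment(sd, 1), tolerance = 0.02)
})

test_that("pde integration conserves mass and preserves positivity", {
  kp <- knowles_params(k_f = 0.016)
  g <- size_grid(2, 500, 250)
  m <- knowles_pde_model(kp, g)
  tt <- seq(0, 30, 1)
  tr <- integrate_pde(m, continuous_state(m, v_star = kp$m0), tt)
  mass <- total_mass(tr)
  expect_lt(max(abs(mass - mass[1])) / mass[1], 1e-3)
  expect_gte(min(tr$u), 0)
  expect_output(print(m), "pde_model")
  # zero initial polymers with k_on = 0: u stays zero, monomers exchange
  m2 <- pde_model(size_grid(2, 50, 24), k_on = 0, k_off = 0,
                  tau = rate_constant(1), k_plus = 1, k_minus = 0.5)
  tr2 <- integrate_pde(m2, continuous_state(m2, v = 2), c(0, 1, 2))
  expect_equal(max(abs(tr2$u)), 0)
  expect_lt(tr2$v[3], 2)
})

test_that("distribution becomes quasi-stationary at intermediate times", {
  # slow-fragmentation corner of the breakable-filament family: once the
  # monomer pool is spent, breakage reshapes the distribution on a much
  # longer timescale and the plateau-phase distribution is near-frozen
  kp <- knowles_params(k_n = 2e-4, k_f = 2e-5)
  g <- size_grid(2, 1500, 500)
  m <- knowles_pde_model(kp, g)
  tt <- seq(0, 30, 0.5)
  tr <- integrate_pde(m, continuous_state(m, v_star = kp$m0), tt)
  expect_gt(min(observable_series(tr, "mean_size")$values[21:61]), 100)
  idx <- which(tt >= 10 & tt <= 20)          # middle third of the run
  normed <- t(apply(tr$u[idx, ], 1, function(u) u / max(sum(u), 1e-30)))
  drift <- max(abs(sweep(normed, 2, normed[1, ])))
  expect_lt(drift / max(normed[1, ]), 0.10)
})

test_that("keep_ratio_term perturbs the monomer balance only slightly", {
  kp <- knowles_params(k_f = 0.016)
  g <- size_grid(2, 500, 250)
  m1 <- knowles_pde_model(kp, g)
  m2 <- knowles_pde_model(kp, g)
  m2$keep_ratio_term <- TRUE
  tt <- seq(0, 20, 1)
  tr1 <- integrate_pde(m1, continuous_state(m1, v_star = kp$m0), tt)
  tr2 <- integrate_pde(m2, continuous_state(m2, v_star = kp$m0), tt)
  expect_lt(compare_models(tr2, tr1, "M1"), 0.02)
  expect_gt(max(abs(tr2$v_star - tr1$v_star)), 0)
})
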