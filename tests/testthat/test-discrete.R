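test_that("rhs vanishes for a zero-rate model and handles pure exchange", {
  m0 <- discrete_model(i0 = 2, N_max = 10, k_on = 0, k_off = 0)
  s <- initial_state(m0, w = 1, v = 2, v_star = 3, c = rep(0.1, 9))
  d <- discrete_rhs(s, m0)
  expect_equal(state_as_vec(d), rep(0, 12))
  mx <- discrete_model(i0 = 2, N_max = 10, k_on = 0, k_off = 0,
                       k_plus = 1, k_minus = 1)
  sx <- initial_state(mx, v = 2, v_star = 0)
  dx <- discrete_rhs(sx, mx)
  expect_equal(dx$v, -2)
  expect_equal(dx$v_star, 2)
  expect_equal(dx$c, rep(0, 9))
  expect_error(discrete_rhs(initial_state(m0, v = NaN), m0), "finite")
})

test_that("R and compiled right-hand sides agree on a full model", {
  for (kind in c("linear_bonds", "mechanical")) {
    m <- random_full_model(frag_kind = kind)
    s <- random_state(m)
    dR <- state_as_vec(discrete_rhs(s, m))
    dC <- amykin:::rhs_discrete_cpp(state_as_vec(s), m$tables)
    expect_equal(dR, as.numeric(dC), tolerance = 1e-13)
  }
})

test_that("mass is conserved without degradation, destroyed with it", {
  m <- random_full_model()
  s <- random_state(m)
  d <- discrete_rhs(s, m)
  sizes <- seq(m$i0, m$N_max)
  expect_equal(d$w + d$v + d$v_star + sum(sizes * d$c), 0,
               tolerance = 1e-12)
  tr <- integrate_discrete(m, s, seq(0, 5, 0.5), method = "lsoda")
  mass <- total_mass(tr)
  expect_lt(max(abs(mass - mass[1])) / mass[1], 1e-6)
  # positivity up to solver tolerance
  expect_gt(min(tr$c), -1e-9)
  mg <- random_full_model(); mg$gamma <- rate_constant(0.2)
  mg$tables <- amykin:::.discrete_tables(mg)
  dg <- discrete_rhs(s, mg)
  expect_lt(dg$w + dg$v + dg$v_star + sum(sizes * dg$c), 0)
})

test_that("pure depolymerization chain matches the matrix-exponential solution", {
  skip_if_not_installed("Matrix")
  kd <- 0.7
  m <- discrete_model(i0 = 2, N_max = 6, k_on = 0, k_off = 0,
                      d = rate_constant(kd))
  # linear system on (v*, c2..c6), c_i at index i: the nucleus does not
  # depolymerize further and each event releases one monomer to v*
  A <- matrix(0, 6, 6)
  for (i in 3:6) {
    A[i, i] <- A[i, i] - kd
    A[i - 1, i] <- A[i - 1, i] + kd
    A[1, i] <- A[1, i] + kd
  }
  y0 <- c(0, 0.3, 0.25, 0.2, 0.15, 0.1)
  tt <- seq(0, 4, 0.5)
  tr <- integrate_discrete(m, initial_state(m, c = y0[-1]), tt,
                           method = "lsoda", rtol = 1e-10, atol = 1e-14)
  for (k in seq_along(tt)) {
    ex <- as.numeric(Matrix::expm(A * tt[k]) %*% y0)
    expect_equal(c(tr$v_star[k], tr$c[k, ]), ex, tolerance = 1e-8)
  }
})

test_that("fragmentation-only dynamics follow the number-moment closed form", {
  k_f <- 0.05
  m <- discrete_model(i0 = 1, N_max = 60, k_on = 0, k_off = 0,
                      frag = fragmentation_kernel("linear_bonds", k_f))
  init <- initial_state(m)
  init$c[40] <- 1                      # monodisperse 40-mers
  tt <- seq(0, 20, 0.5)
  tr <- integrate_discrete(m, init, tt, method = "lsoda")
  M0 <- traj_moment(tr, 0); M1 <- traj_moment(tr, 1)
  expect_lt(max(abs(M1 - M1[1])), 1e-8)               # frag conserves mass
  expect_true(all(diff(M0) > 0))                      # number grows
  pred <- M1 + (M0[1] - M1) * exp(-k_f * tt)
  expect_lt(max(abs(M0 - pred)), 1e-6)
  # coalescence-only: M1 constant, M0 non-increasing
  mc <- discrete_model(i0 = 2, N_max = 80, k_on = 0, k_off = 0,
                       coag = coalescence_kernel(0.05))
  ic <- initial_state(mc); ic$c[seq(1, 20)] <- 0.2
  trc <- integrate_discrete(mc, ic, tt, method = "lsoda")
  expect_lt(max(abs(traj_moment(trc, 1) - traj_moment(trc, 1)[1])), 1e-6)
  expect_true(all(diff(traj_moment(trc, 0)) < 1e-12))
})

test_that("nucleation-dissociation equilibrium reaches detailed balance", {
  m <- discrete_model(i0 = 2, N_max = 10, k_on = 0.3, k_off = 2)
  tr <- integrate_discrete(m, initial_state(m, v_star = 4),
                           seq(0, 60, 2), method = "lsoda", rtol = 1e-10)
  vs <- tr$v_star[31]
  expect_equal(tr$c[31, 1], m$k_on * vs^2 / m$k_off, tolerance = 1e-6)
})

test_that("moments match direct summation and rk4 matches lsoda", {
  m <- random_full_model()
  s <- random_state(m, seed = 4)
  sizes <- seq(m$i0, m$N_max)
  for (ord in 0:2)
    expect_equal(state_moment(s, ord), sum(sizes^ord * s$c))
  expect_equal(discrete_moment(s, 1), state_moment(s, 1))
  expect_error(state_moment(s, 3), "order")
  s0 <- initial_state(m)
  expect_equal(state_moment(s0, 0), 0)
  s1 <- initial_state(m); s1$c[10 - m$i0 + 1] <- 2
  expect_equal(sapply(0:2, state_moment, state = s1), c(2, 20, 200))
  tt <- seq(0, 4, 0.5)
  tr1 <- integrate_discrete(m, s, tt, method = "lsoda")
  # rk4 is the stability-bounded fast path; agreement at the level the
  # fitting loop needs, not at lsoda's tolerance
  tr2 <- integrate_discrete(m, s, tt, method = "rk4")
  expect_lt(max(abs(traj_moment(tr1, 1) - traj_moment(tr2, 1))) /
              max(traj_moment(tr1, 1)), 1e-3)
  expect_error(integrate_discrete(m, s, c(0, 1, 1)), "increasing")
})

test_that("zero-rate model yields a constant trajectory and trajectories print", {
  m <- discrete_model(i0 = 2, N_max = 8, k_on = 0, k_off = 0)
  s <- initial_state(m, w = 1, v = 0.5, v_star = 0.25, c = rep(0.1, 7))
  tr <- integrate_discrete(m, s, seq(0, 10, 1))
  expect_equal(tr$w, rep(1, 11))
  expect_equal(tr$c[11, ], tr$c[1, ])
  expect_output(print(tr), "discrete_trajectory")
  df <- as.data.frame(tr)
  expect_named(df, c("t", "w", "v", "v_star", "M0", "M1", "M2"))
  tmp <- tempfile(fileext = ".csv")
  write_trajectory_csv(tr, tmp)
  back <- utils::read.csv(tmp)
  expect_equal(back$c8[1], 0.1)
})

test_that("model construction validates its inputs", {
  expect_error(discrete_model(i0 = 0, N_max = 5, k_on = 0, k_off = 0), "i0")
  expect_error(discrete_model(i0 = 5, N_max = 5, k_on = 0, k_off = 0), "N_max")
  expect_error(discrete_model(i0 = 2, N_max = 5, k_on = -1, k_off = 0), ">= 0")
})
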