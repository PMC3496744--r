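test_that("ThT and SLS signals are the restricted first and second moments", {
  m <- random_full_model(coag = FALSE)
  s <- random_state(m, seed = 9)
  tr <- integrate_discrete(m, s, seq(0, 3, 0.5), method = "lsoda")
  sizes <- seq(m$i0, m$N_max)
  # threshold 0 equals M1
  expect_equal(tht_signal(tr, threshold = 0)$values, traj_moment(tr, 1))
  # direct recomputation above a threshold
  thr <- 10
  expect_equal(tht_signal(tr, thr)$values,
               as.numeric(tr$c %*% (sizes * (sizes >= thr))))
  # everything below the threshold gives zero signal
  expect_equal(tht_signal(tr, m$N_max + 1)$values, rep(0, 7))
  expect_equal(sls_signal(tr)$values, traj_moment(tr, 2))
  s1 <- initial_state(m); s1$c[10 - m$i0 + 1] <- 2
  tr1 <- integrate_discrete(discrete_model(i0 = 2, N_max = 30, k_on = 0, k_off = 0),
                            s1, c(0, 1))
  expect_equal(sls_signal(tr1)$values, c(200, 200))
})

test_that("ThT is monotone for growth-only models", {
  p <- polyq_params()
  tr <- simulate_polyq(polyq_model(p), seq(0, 48, 1), method = "lsoda")
  expect_true(all(diff(tht_signal(tr)$values) > -1e-10))
})

test_that("transition parameters recover the logistic closed form", {
  A <- 7; r <- 1.5; t0 <- 8
  t <- seq(0, 20, 0.05)
  ts <- time_series(t, A / (1 + exp(-r * (t - t0))))
  p <- transition_params(ts)
  expect_equal(p$max_slope, A * r / 4, tolerance = 1e-3)
  expect_equal(p$inflexion_time, t0, tolerance = 0.05)
  # baseline is ~0 at t=0 here; tangent intercept = t0 - 2/r
  expect_equal(p$lag_time, t0 - 2 / r, tolerance = 0.02)
  # affine invariance of the signal axis: lag unchanged, slope scales
  ts2 <- time_series(t, 3 * ts$values + 5)
  p2 <- transition_params(ts2)
  expect_equal(p2$lag_time, p$lag_time, tolerance = 1e-9)
  expect_equal(p2$max_slope, 3 * p$max_slope, tolerance = 1e-9)
  expect_lte(p$lag_time, p$inflexion_time)
})

test_that("transition parameters handle ramps and degenerate curves", {
  t <- seq(0, 10, 0.5)
  ramp <- time_series(t, pmax(t - 4, 0))
  p <- transition_params(ramp)
  expect_equal(p$lag_time, 4, tolerance = 0.5)
  expect_error(transition_params(time_series(t, rep(1, length(t)))),
               "no inflexion")
  expect_error(transition_params(time_series(0:3, 0:3)), "at least 5")
})

test_that("coalescence widens the ThT/SLS plateau-time gap", {
  p <- polyq_params()
  run <- function(coag_on) {
    mm <- discrete_model(i0 = 1, N_max = 120, k_on = p$k_on, k_off = p$k_off,
                         tau = rate_piecewise_linear(p$x1, p$x2, p$x3, p$tau_max),
                         coag = if (coag_on) coalescence_kernel(0.02) else NULL,
                         k_plus = p$k_plus, k_minus = p$k_minus, k_act = p$k_act)
    integrate_discrete(mm, initial_state(mm, w = 40),
                       seq(0, 60, length.out = 120), method = "lsoda")
  }
  tr_off <- run(FALSE); tr_on <- run(TRUE)
  gap_off <- coalescence_diagnostic(tht_signal(tr_off), sls_signal(tr_off))
  gap_on <- coalescence_diagnostic(tht_signal(tr_on), sls_signal(tr_on))
  expect_gt(gap_on, gap_off + 2)       # coalescence keeps M2 growing
  # identical curves: zero gap
  expect_equal(coalescence_diagnostic(tht_signal(tr_off), tht_signal(tr_off)), 0)
  # unreachable plateau fraction errors
  t <- seq(0, 10, 0.1)
  rising <- time_series(t, t)          # plateau value ~9.8, never 0.95x at start
  expect_error(coalescence_diagnostic(time_series(t, rep(0, 101)), rising),
               "plateau")
})
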