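test_that("moment right-hand side matches direct evaluation", {
  kp <- knowles_params(k_p = 3, k_f = 0, k_n = 0)
  d <- knowles_moment_rhs(m = 1, M = 0, P = 1, kp)
  expect_equal(unname(d["dM"]), 6)          # n_ends * k_p * m * P
  expect_equal(unname(d["dm"]), -6)
  expect_equal(unname(d["dP"]), 0)
  # all-zero polymers and no nucleation: nothing moves
  expect_equal(unname(knowles_moment_rhs(2, 0, 0, kp)), c(0, 0, 0))
  # fragmentation and nucleation terms
  kp2 <- knowles_params(k_p = 0, k_f = 0.1, k_n = 1e-3)
  d2 <- knowles_moment_rhs(m = 2, M = 5, P = 0.5, kp2)
  expect_equal(unname(d2["dP"]), 0.1 * (5 - 3 * 0.5) + 1e-3 * 4)
  expect_equal(unname(d2["dM"]), 2 * 1e-3 * 4 - 2 * 0.1 * 0.5)
})

test_that("discrete system reduces exactly to the two-moment system", {
  kp <- knowles_params(k_f = 0.016)      # smaller mean size, fast check
  N <- round(10 * knowles_mean_size(kp))
  dm <- knowles_discrete_model(kp, N_max = N)
  tt <- seq(0, 25, 0.5)
  trd <- integrate_discrete(dm, initial_state(dm, v_star = kp$m0), tt,
                            method = "rk4")
  expect_lt(trd$diagnostics$leak_frac, 1e-4)
  mo <- knowles_moments(kp, tt)
  expect_lt(max(abs(trd$v_star - mo$m)) / max(mo$m), 1e-3)
  expect_lt(max(abs(traj_moment(trd, 1) - mo$M)) / max(mo$M), 1e-3)
  expect_lt(max(abs(traj_moment(trd, 0) - mo$P)) / max(mo$P), 1e-3)
})

test_that("mean size rises fast and then declines slowly", {
  kp <- knowles_params(k_f = 0.016)
  tt <- seq(0, 60, 0.5)
  N <- round(10 * knowles_mean_size(kp))
  dm <- knowles_discrete_model(kp, N_max = N)
  tr <- integrate_discrete(dm, initial_state(dm, v_star = kp$m0), tt,
                           method = "rk4")
  ms <- observable_series(tr, "mean_size")$values
  peak <- which.max(ms)
  expect_lt(tt[peak], 20)
  expect_gt(ms[peak], 60)
  expect_lt(ms[length(ms)], ms[peak])        # ultimately the mean decays
})

test_that("PDE model matches the moment system on mass", {
  kp <- knowles_params()
  ms <- knowles_mean_size(kp)
  g <- size_grid(2, round(8 * ms), round(4 * ms))
  pm <- knowles_pde_model(kp, g)
  expect_equal(pm$n_nuc, 2)
  expect_equal(pm$k_off, 0)
  tt <- seq(0, 30, 0.5)
  trp <- integrate_pde(pm, continuous_state(pm, v_star = kp$m0), tt)
  mo <- knowles_moments(kp, tt)
  expect_lt(compare_models(trp, mo, "M1"), 0.02)
})

test_that("relative L2 comparison behaves as a metric ratio", {
  tt <- seq(0, 10, 0.5)
  a <- time_series(tt, sin(tt) + 2)
  mk <- function(v) {
    structure(list(t = tt, m = v, M = v, P = rep(1, length(tt))),
              class = "data.frame", row.names = seq_along(tt))
  }
  expect_equal(compare_models(mk(a$values), mk(a$values), "M1"), 0)
  expect_equal(compare_models(mk(2 * a$values), mk(a$values), "M1"), 1)
  expect_error(compare_models(mk(a$values), mk(rep(0, 21)), "M1"),
               "zero norm")
})
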