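test_that("adimensioned L2 error matches hand arithmetic", {
  cu <- experimental_curve(0:2, c(0, 1, 2), w0 = 10)
  expect_equal(adimensioned_l2_error(c(0, 1, 1), cu), sqrt(1 / 5))
  expect_equal(adimensioned_l2_error(c(0, 1, 2), cu), 0)
  expect_equal(adimensioned_l2_error(c(0, 0, 0), cu), 1)
  # joint rescaling of both signal axes leaves the error unchanged
  cu2 <- experimental_curve(0:2, 7 * c(0, 1, 2), w0 = 10)
  expect_equal(adimensioned_l2_error(7 * c(0, 1, 1), cu2), sqrt(1 / 5))
  expect_error(adimensioned_l2_error(c(0, 0, 0),
                                     experimental_curve(0:2, c(0, 0, 0), 1)),
               "zero norm")
  # a time_series that does not cover the data range errors
  expect_error(adimensioned_l2_error(time_series(0:1, c(0, 1)), cu), "cover")
})

test_that("curve and dataset constructors validate their inputs", {
  expect_error(experimental_curve(c(0, 1, 1), c(0, 1, 2), 1), "increasing")
  expect_error(experimental_curve(0:2, c(0, NA, 2), 1), "finite")
  expect_error(fit_config(n_starts = 0), "n_starts")
  cfg <- fit_config(seed = 5)
  expect_s3_class(cfg, "fit_config")
  expect_named(cfg$bounds)
})

test_that("fast and generic objectives agree and reward the truth", {
  p <- polyq_params()
  ds <- generate_tht_dataset(p, w0_list = c(20, 40), noise_sd = 0, seed = 3)
  cfg <- fit_config(seed = 1)
  obj_fast <- amykin:::.polyq_objective(ds$curves, 1, cfg)
  obj_slow <- amykin:::.polyq_objective_slow(ds$curves, 1, cfg)
  lp_truth <- log10(unlist(p[names(cfg$bounds)]))
  expect_lt(obj_fast(lp_truth), 1e-10)
  for (k in 1:3) {
    lp <- lp_truth + runif(6, -0.3, 0.3)
    expect_equal(obj_fast(lp), obj_slow(lp), tolerance = 1e-6)
    expect_gt(obj_fast(lp), obj_fast(lp_truth))
  }
})

test_that("fits are deterministic and refinement never worsens the incumbent", {
  p <- polyq_params()
  ds <- generate_tht_dataset(p, noise_sd = 0.01, seed = 11)
  cfg <- fit_config(n_starts = 2, n_refine_starts = 2, max_evals = 60,
                    seed = 99)
  f1 <- fit_polyq(ds$curves, i0 = 1, config = cfg)
  f2 <- fit_polyq(ds$curves, i0 = 1, config = cfg)
  expect_identical(coef(f1), coef(f2))
  expect_identical(f1$global_error, f2$global_error)
  tr <- f1$trace
  expect_lte(min(tr[tr[, "phase"] == 2, "value"]),
             min(tr[tr[, "phase"] == 1, "value"]) + 1e-12)
  expect_output(print(f1), "agg_fit")
  expect_named(coef(f1), names(cfg$bounds))
  expect_equal(length(residuals(f1)), 3)
  pr <- predict(f1, w0 = 30, times = seq(0, 48, 4))
  expect_s3_class(pr, "time_series")
})

test_that("separate fits show larger parameter spread than the shared truth", {
  p <- polyq_params()
  ds <- generate_tht_dataset(p, noise_sd = 0.01, seed = 21)
  cfg <- fit_config(n_starts = 2, n_refine_starts = 1, max_evals = 120,
                    seed = 7)
  fs <- fit_polyq(ds$curves, i0 = 1, mode = "separate", config = cfg)
  expect_equal(nrow(fs$par_matrix), 3)
  expect_true(all(fs$per_curve_errors < 0.2))
  spread <- apply(log10(fs$par_matrix), 2, stats::sd)
  expect_gt(max(spread), 0)
})

test_that("nucleus-size selection returns a tabulated, tie-stable answer", {
  p <- polyq_params()
  ds <- generate_tht_dataset(p, noise_sd = 0.01, seed = 31)
  cfg <- fit_config(n_starts = 1, n_refine_starts = 1, max_evals = 40,
                    seed = 13)
  tab <- select_nucleus_size(ds$curves, i0_candidates = c(1, 2), config = cfg)
  expect_s3_class(tab, "i0_selection")
  expect_equal(tab$i0, c(1, 2))
  expect_true(all(tab$global_error >= 0))
  single <- select_nucleus_size(ds$curves, i0_candidates = 2, config = cfg)
  expect_equal(nrow(single), 1)
  expect_equal(attr(single, "best"), 2)
})

test_that("data from irreversible activation report k_minus as negligible", {
  # truth has no reverse conversion: freezing k_minus at zero must fit
  # as well as leaving it free (the reverse step carries no signal),
  # and the free fit keeps it small against the forward rate
  p <- polyq_params(k_minus = 0)
  ds <- generate_tht_dataset(p, noise_sd = 0.01, seed = 55)
  cfg <- fit_config(n_starts = 12, n_refine_starts = 6, max_evals = 800,
                    seed = 17)
  free <- fit_polyq(ds$curves, i0 = 1, config = cfg)
  frozen <- fit_polyq(ds$curves, i0 = 1, config = cfg,
                      fixed = list(k_minus = 0))
  expect_lt(frozen$global_error, free$global_error + 0.002)
  expect_lt(coef(free)[["k_minus"]], 0.15 * coef(free)[["k_plus"]])
  expect_lt(free$global_error, 0.05)
})
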