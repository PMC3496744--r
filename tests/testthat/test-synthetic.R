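test_that("noise-free synthetic curves equal the model output exactly", {
  p <- polyq_params()
  tt <- seq(0, 48, length.out = 25)
  ds <- generate_tht_dataset(p, w0_list = 40, times = tt, noise_sd = 0, seed = 1)
  sim <- amykin:::.polyq_tht(p, tt)
  expect_equal(ds$curves[[1]]$values, sim$values)
  expect_equal(ds$curves[[1]]$w0, 40)
})

test_that("generation is bit-identical under a fixed seed", {
  p <- polyq_params()
  d1 <- generate_tht_dataset(p, noise_sd = 0.02, seed = 42)
  d2 <- generate_tht_dataset(p, noise_sd = 0.02, seed = 42)
  expect_identical(d1$curves, d2$curves)
  d3 <- generate_tht_dataset(p, noise_sd = 0.02, seed = 43)
  expect_false(identical(d1$curves[[1]]$values, d3$curves[[1]]$values))
})

test_that("noisy replicates average back to the noiseless curve", {
  p <- polyq_params()
  tt <- seq(0, 48, length.out = 6)       # few points, many replicates
  clean <- amykin:::.polyq_tht(p, tt)$values
  plat <- mean(clean[6])
  nrep <- 200
  acc <- matrix(0, nrep, length(tt))
  for (r in 1:nrep)
    acc[r, ] <- generate_tht_dataset(p, w0_list = 40, times = tt,
                                     noise_sd = 0.05, seed = r)$curves[[1]]$values
  se <- 0.05 * plat / sqrt(nrep)
  expect_true(all(abs(colMeans(acc) - clean) < 3 * se + 1e-12))
})

test_that("noiseless curves are sigmoidal with a lag whenever nucleation limits", {
  p <- polyq_params()
  for (w0 in c(20, 40, 60)) {
    ds <- generate_tht_dataset(p, w0_list = w0, noise_sd = 0, seed = 1)
    tp <- transition_params(time_series(ds$curves[[1]]$times,
                                        ds$curves[[1]]$values))
    expect_gt(tp$lag_time, 1)
    expect_gt(tp$max_slope, 0)
  }
})

test_that("datasets round-trip through the CSV + manifest format", {
  p <- polyq_params()
  ds <- generate_tht_dataset(p, noise_sd = 0.01, seed = 5)
  dir <- tempfile("ds")
  write_dataset(ds, dir)
  expect_true(file.exists(file.path(dir, "manifest.yaml")))
  back <- read_dataset(dir)
  expect_equal(length(back), 3)
  for (k in 1:3) {
    expect_equal(back[[k]]$w0, ds$curves[[k]]$w0)
    expect_equal(back[[k]]$values, ds$curves[[k]]$values, tolerance = 1e-12)
  }
})

test_that("model configuration files load into parameter objects", {
  p <- read_model_config(system.file("extdata", "polyq.yaml",
                                     package = "amykin"))
  expect_s3_class(p, "polyq_params")
  expect_equal(p$i0, 1L)
  extra <- attr(p, "extra")
  expect_equal(unlist(extra$w0_list), c(20, 40, 60))
  k <- read_model_config(system.file("extdata", "knowles.yaml",
                                     package = "amykin"))
  expect_s3_class(k, "knowles_params")
  x <- read_model_config(system.file("extdata", "xue.yaml",
                                     package = "amykin"))
  expect_s3_class(x, "xue_params")
  expect_error(read_model_config(tempfile()), "not found")
})

test_that("a single-replicate zero-noise recovery run is unbiased", {
  p <- polyq_params()
  cfg <- fit_config(n_starts = 3, n_refine_starts = 2, max_evals = 250,
                    seed = 2)
  rep1 <- recovery_experiment(p, cfg, n_replicates = 1, noise_sd = 0,
                              seed = 8, w0_list = c(20, 40, 60))
  expect_s3_class(rep1, "recovery_report")
  expect_lt(rep1$global_errors[1], 0.05)
  expect_identical(
    recovery_experiment(p, cfg, n_replicates = 1, noise_sd = 0, seed = 8)$estimates,
    rep1$estimates)
})
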