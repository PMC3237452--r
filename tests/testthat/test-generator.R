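test_that("default panel matches the published metabolite order", {
  p <- default_panel()
  expect_length(p, 25L)
  expect_false(anyDuplicated(p) > 0)
  expect_identical(p[3L], "Albumin")
  expect_identical(p[5L], "Arginine")
  expect_identical(p[9L], "Glutamate")
  expect_identical(p[14L], "Lactate")
  expect_identical(p[18L], "Ornithine")
  expect_identical(p[23L], "Tyrosine")
})

test_that("noise-free, factor-free batches equal the linear mean surface", {
  cfg <- generator_config(n_fresh = 2L, n_latent = 0L, noise_sd = 0,
                          seed = 5L)
  ds <- generate_fresh(cfg)
  mu <- outer(cfg$baseline_intercepts, rep(1, 6)) +
    outer(cfg$baseline_slopes, 1:6)
  expect_equal(unname(get_batch(ds, 1L)), mu)
  expect_identical(get_batch(ds, 1L), get_batch(ds, 2L))
})

test_that("generation is deterministic given the seed", {
  cfg <- generator_config(seed = 11L)
  expect_identical(generate_fresh(cfg)$values, generate_fresh(cfg)$values)
  expect_identical(generate_study(cfg)$values, generate_study(cfg)$values)
  cfg2 <- generator_config(seed = 12L)
  expect_false(identical(generate_fresh(cfg)$values,
                         generate_fresh(cfg2)$values))
})

test_that("per-column sample means converge to the linear mean surface", {
  cfg <- generator_config(n_fresh = 200L, n_latent = 0L, seed = 1L)
  ds <- generate_fresh(cfg)
  mu <- outer(cfg$baseline_intercepts, rep(1, 6)) +
    outer(cfg$baseline_slopes, 1:6)
  bar <- mean_trajectory(ds)
  expect_true(all(abs(bar - mu) < 4 * 0.15 / sqrt(200)))
})

test_that("zero perturbation makes WI batches identical to fresh", {
  cfg <- generator_config(n_fresh = 6L, n_wi = 6L, seed = 3L)
  cfg$wi_perturbation[] <- 0
  expect_equal(generate_wi(cfg)$values, generate_fresh(cfg)$values,
               ignore_attr = TRUE)
})

test_that("the default WI surface carries the published signs and timing", {
  cfg <- generator_config(n_fresh = 6L, n_wi = 6L, seed = 3L)
  # same seed: WI minus fresh is exactly the perturbation surface
  delta <- generate_wi(cfg)$values[1L, , ] - generate_fresh(cfg)$values[1L, , ]
  rownames(delta) <- cfg$panel
  expect_lt(delta["Ornithine", 1L], 0)
  expect_true(all(delta["Ornithine", 2:6] > 0))
  expect_true(all(delta["Albumin", ] < 0))
  expect_identical(unname(which.min(delta["Arginine", ])), 4L)
  expect_true(all(delta["Tyrosine", 5:6] > 0))
  expect_gt(delta["Lactate", 1L], 0)
})

test_that("anomaly injection corrupts exactly what it is told to", {
  ds <- default_study(seed = 2L)
  expect_identical(inject_anomalies(ds)$values, ds$values)
  bad <- inject_anomalies(ds, negative_cells = data.frame(
    batch = 4L, metabolite = "Lactate", hour = 3L))
  expect_identical(sum(bad$values < 0), 1L)
  expect_lt(bad$values[4L, 14L, 3L], 0)
  expect_gt(ds$values[4L, 14L, 3L], 0) # original untouched
  expect_error(inject_anomalies(ds, negative_cells = data.frame(
    batch = 99L, metabolite = 1L, hour = 1L)), "out of range")
})

test_that("a wholesale-shifted batch lands outside the 99% score ellipse", {
  ds <- default_study(seed = 4L)
  shifted <- inject_anomalies(ds, shift_batches = "F03", shift_sd = 10)
  model <- fit_mpca(shifted, R = 3L)
  out <- detect_outlier_batches(model, shifted, alpha = 0.01)
  expect_identical(out, "F03")
  scr <- screen_outliers(shifted, R = 3L)
  expect_identical(scr$excluded, "F03")
  expect_identical(n_batches(scr$dataset), 15L)
})

test_that("fresh and WI batches separate linearly in the first two scores", {
  ds <- default_study(seed = 6L)
  model <- fit_mpca(ds, R = 3L)
  sc <- model$scores[, 1:2, drop = FALSE]
  is_wi <- ds$labels == "wi"
  # project onto the between-class direction: clusters must not overlap
  dir <- colMeans(sc[is_wi, ]) - colMeans(sc[!is_wi, ])
  proj <- sc %*% dir
  expect_gt(min(proj[is_wi]), max(proj[!is_wi]))
})

test_that("three latent factors dominate the scaled fresh covariance", {
  model <- fit_mpca(generate_fresh(generator_config(seed = 3L)), R = 3L)
  expect_gte(100 * sum(model$explained_variance[1:3]), 65)
})

test_that("generator configs are validated", {
  expect_error(generator_config(n_time = 0L), "n_time")
  expect_error(generator_config(noise_sd = -1), "noise_sd")
  expect_error(generator_config(baseline_slopes = 1:3), "per metabolite")
  expect_error(generator_config(factor_loadings = matrix(0, 2, 10)),
               "factor_loadings")
})
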