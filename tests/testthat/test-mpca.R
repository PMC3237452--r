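fresh_model <- local({
  ds <- generate_fresh(generator_config(seed = 1L))
  fit_mpca(ds, R = 3L)
})

test_that("degenerate training data is rejected", {
  vals <- array(rep(as.numeric(1:150), each = 4L), c(4L, 25L, 6L))
  ds <- batch_dataset(vals, rep("fresh", 4L))
  expect_error(suppressMessages(fit_mpca(ds, R = 1L)), "degenerate")
  expect_error(fit_mpca(generate_fresh(generator_config(seed = 1L)),
                        R = 20L), "rank")
})

test_that("loadings match a dense eigen-decomposition of the covariance", {
  ds <- random_dataset(I = 8L, J = 25L, K = 6L, seed = 21L,
                       labels = rep("fresh", 8L))
  model <- fit_mpca(ds, R = 3L)
  Xs <- scale_oracle(unfold(ds, "batchwise")$matrix)
  ev <- eigen(cov(Xs), symmetric = TRUE)$vectors[, 1:3]
  for (r in 1:3) {
    expect_equal(abs(sum(model$loadings[, r] * ev[, r])), 1,
                 tolerance = 1e-8)
  }
})

test_that("model dimensions and invariants hold on study-sized data", {
  m <- fresh_model
  expect_identical(dim(m$loadings), c(150L, 3L))
  expect_identical(dim(m$scores), c(10L, 3L))
  ortho <- crossprod(m$loadings) - diag(3L)
  expect_lt(max(abs(ortho)), 1e-8)
  expect_true(all(diff(m$explained_variance) <= 1e-12))
  expect_true(all(m$limits_online["alpha_0.01", ] >=
                    m$limits_online["alpha_0.05", ]))
  expect_gte(m$limits_offline["alpha_0.01"], m$limits_offline["alpha_0.05"])
})

test_that("projection reproduces the dense residual oracle", {
  m <- fresh_model
  # mean-surface batch: scores and residuals vanish
  pr0 <- project_batch(m, m$scaler$means)
  expect_lt(max(abs(pr0$scores)), 1e-12)
  expect_lt(max(abs(pr0$residuals)), 1e-12)
  # in-plane batch
  t_in <- matrix(c(2, -1, 0.5), 1L)
  x_in <- matrix(t_in %*% t(m$loadings), m$J, m$K)
  b_in <- x_in * m$scaler$sds + m$scaler$means
  pr_in <- project_batch(m, b_in)
  expect_equal(unname(pr_in$scores), unname(t_in), tolerance = 1e-10)
  expect_lt(max(abs(pr_in$residuals)), 1e-10)
  # random batch vs brute-force (I - PP')x
  set.seed(77)
  b <- m$scaler$means + matrix(rnorm(150), m$J, m$K)
  pr <- project_batch(m, b)
  x <- matrix(as.vector((b - m$scaler$means) / m$scaler$sds), 1L)
  expect_equal(pr$residuals, dense_residual(m$loadings, x),
               tolerance = 1e-10)
  expect_equal(spe_offline(m, b)$spe,
               sum(dense_residual(m$loadings, x)^2), tolerance = 1e-10)
})

test_that("completeness: R = min(I-1, JK) drives training SPE to zero", {
  ds <- generate_fresh(generator_config(n_fresh = 8L, seed = 13L))
  m <- suppressMessages(fit_mpca(ds, R = 7L))
  expect_lt(max(m$spe_train_offline), 1e-10)
  expect_true(all(is.na(m$limits_offline)))
})

test_that("online scores equal the truncated least-squares oracle", {
  m <- fresh_model
  set.seed(42)
  b <- m$scaler$means + matrix(rnorm(150, sd = 0.3), m$J, m$K)
  # k = K reduces to the full projection
  osK <- online_scores(m, b, m$K)
  expect_equal(osK$scores, project_batch(m, b)$scores, tolerance = 1e-8)
  # mean-surface partial trajectory
  os0 <- online_scores(m, m$scaler$means[, 1:3], 3L)
  expect_lt(max(abs(os0$scores)), 1e-12)
  # independent normal-equations oracle at k = 3
  k <- 3L
  xs <- as.vector((b[, 1:k] - m$scaler$means[, 1:k]) / m$scaler$sds[, 1:k])
  Pk <- m$loadings[seq_len(m$J * k), ]
  t_or <- solve(crossprod(Pk), crossprod(Pk, xs))
  os <- online_scores(m, b[, 1:k], k)
  expect_equal(as.vector(os$scores), as.vector(t_or), tolerance = 1e-8)
  expect_error(online_scores(m, b, 7L), "out of range")
})

test_that("online SPE matches brute force in both windows", {
  m <- fresh_model
  expect_true(all(spe_online(m, m$scaler$means)$spe < 1e-20))
  set.seed(43)
  b <- m$scaler$means + matrix(rnorm(150, sd = 0.5), m$J, m$K)
  for (k in c(1L, 3L, 6L)) {
    os <- online_scores(m, b[, 1:k, drop = FALSE], k)
    e <- os$residuals
    inst <- sum(e[1L, (k - 1L) * m$J + seq_len(m$J)]^2)
    cum <- sum(e^2)
    expect_equal(spe_online(m, b, k)$spe, inst, tolerance = 1e-10)
    expect_equal(spe_online(m, b, k, mode = "cumulative")$spe, cum,
                 tolerance = 1e-10)
  }
})

test_that("scaled chi-squared limits match the quantile oracle", {
  # moments m=2, v=4: g = 1, h = 2
  s <- c(1.575829, 0.2, 4.424171, 1.8)  # mean 2, var 4 (up to tol)
  s <- s + (2 - mean(s))
  s <- (s - 2) * sqrt(4 / var(s)) + 2
  lim <- spe_limit(s, 0.05)
  expect_equal(unname(lim), qchisq(0.95, df = 2), tolerance = 1e-10)
  # self-consistency on a large chi-squared sample
  set.seed(7)
  h <- 6
  samp <- rchisq(200000, df = h)
  expect_equal(unname(spe_limit(samp, 0.05)), qchisq(0.95, h),
               tolerance = 0.02)
  expect_gt(spe_limit(samp, 0.01), spe_limit(samp, 0.05))
  expect_error(spe_limit(rep(3, 10)), "degenerate")
  expect_error(spe_limit(c(1, 2)), ">= 3")
})

test_that("contributions conserve the SPE and carry signs", {
  m <- fresh_model
  t_in <- matrix(c(1, 1, -2), 1L)
  b_in <- matrix(t_in %*% t(m$loadings), m$J, m$K) * m$scaler$sds +
    m$scaler$means
  ct0 <- contributions(m, b_in)
  expect_lt(max(ct0$squared), 1e-18)
  set.seed(99)
  b <- m$scaler$means + matrix(rnorm(150, sd = 0.4), m$J, m$K)
  ct <- contributions(m, b)
  expect_true(all(ct$squared >= 0))
  expect_equal(sum(ct$squared), spe_offline(m, b)$spe, tolerance = 1e-10)
  expect_equal(sum(ct$squared), ct$spe, tolerance = 1e-12)
})

test_that("WI batches run below fresh albumin in the normalized errors", {
  ds <- default_study(seed = 7L)
  m <- fit_mpca(subset_batches(ds, ds$labels == "fresh"), R = 3L)
  for (i in which(ds$labels == "wi")[1:3]) {
    ct <- contributions(m, get_batch(ds, i))
    expect_true(all(ct$normalized["Albumin", ] < 0))
  }
})

test_that("the 3-sigma band isolates an injected single fault", {
  ds <- generate_fresh(generator_config(n_fresh = 20L, seed = 31L))
  m <- fit_mpca(ds, R = 3L)
  held <- generate_fresh(generator_config(n_fresh = 1L, seed = 32L))
  b <- get_batch(held, 1L)
  b["Ornithine", 2L] <- b["Ornithine", 2L] + 8 * m$scaler$sds[18L, 2L]
  fl <- flag_contributors(m, contributions(m, b))
  expect_true(any(fl$metabolite == "Ornithine" & fl$hour == 2L))
  expect_lte(nrow(fl), 3L)
  # squared-contribution variant flags it too
  fl2 <- flag_contributors(m, contributions(m, b), statistic = "squared")
  expect_true(any(fl2$metabolite == "Ornithine" & fl2$hour == 2L))
})

test_that("ornithine is flagged at hour 2 for default WI batches", {
  ds <- default_study(seed = 7L)
  m <- fit_mpca(subset_batches(ds, ds$labels == "fresh"), R = 3L)
  for (i in which(ds$labels == "wi")) {
    fl <- flag_contributors(m, contributions(m, get_batch(ds, i)))
    expect_true(any(fl$metabolite == "Ornithine" & fl$hour == 2L))
  }
})

test_that("score ellipses nest and the origin lies inside", {
  m <- fresh_model
  e95 <- score_ellipse(m, alpha = 0.05)
  e99 <- score_ellipse(m, alpha = 0.01)
  expect_true(all(e99$semi_axes >= e95$semi_axes))
  ds <- generate_fresh(generator_config(seed = 1L))
  out99 <- detect_outlier_batches(m, ds, alpha = 0.01)
  out95 <- detect_outlier_batches(m, ds, alpha = 0.05)
  expect_true(all(out99 %in% out95))
  expect_error(score_ellipse(fit_mpca(ds, R = 1L)), "R >= 2")
})

test_that("mean online SPE rises monotonically with ischemia severity", {
  base <- generator_config(seed = 19L)
  ds_f <- generate_fresh(base)
  m <- fit_mpca(ds_f, R = 3L)
  mean_spe <- sapply(c(1, 2, 4), function(cc) {
    cfg <- base
    cfg$wi_perturbation <- cfg$wi_perturbation * cc
    cfg$seed <- 99L # matched across severities
    tr <- spe_online_dataset(m, generate_wi(cfg))
    tapply(tr$spe, tr$hour, mean)
  })
  expect_true(all(mean_spe[, 2] >= mean_spe[, 1]))
  expect_true(all(mean_spe[, 3] >= mean_spe[, 2]))
})

test_that("WI batches exceed the 99% limits and the 1.35 log index", {
  ds <- default_study(seed = 7L)
  m <- fit_mpca(subset_batches(ds, ds$labels == "fresh"), R = 3L)
  wi <- subset_batches(ds, ds$labels == "wi")
  off <- spe_offline(m, wi)
  expect_true(all(off$exceeds_alpha_0.01))
  tr <- spe_online_dataset(m, wi)
  expect_true(all(tr$exceeds_alpha_0.01))
  expect_true(all(tr$index_flag))
  fresh_off <- spe_offline(m, subset_batches(ds, ds$labels == "fresh"))
  expect_true(all(!fresh_off$index_flag))
})
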