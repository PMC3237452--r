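test_that("dummy coding follows the fixed class order", {
  expect_identical(unname(encode_classes("fresh")$matrix), matrix(c(1, 0), 1L))
  expect_identical(unname(encode_classes("wi")$matrix), matrix(c(0, 1), 1L))
  y <- encode_classes(c("fresh", "wi", "fresh"))
  expect_identical(unname(y$matrix),
                   matrix(c(1, 0, 0, 1, 1, 0), 3L, byrow = TRUE))
  expect_true(all(rowSums(y$matrix) == 1))
  expect_error(encode_classes(c("fresh", "marginal")), "unseen")
})

test_that("first NIPALS weight equals the dominant eigenvector of X'YY'X", {
  for (seed in 1:5) {
    ds <- random_dataset(I = 6L, J = 4L, K = 2L, seed = seed)
    model <- suppressWarnings(fit_mpls(ds, R = 1L))
    Xs <- scale_oracle(unfold(ds, "batchwise")$matrix)
    Yc <- scale(encode_classes(ds$labels)$matrix, scale = FALSE)
    A <- t(Xs) %*% Yc %*% t(Yc) %*% Xs
    v1 <- eigen(A, symmetric = TRUE)$vectors[, 1L]
    expect_equal(abs(sum(model$weights[, 1L] * v1)), 1, tolerance = 1e-6)
  }
})

test_that("a separable direction is found with near-total Y variance", {
  cfg <- generator_config(n_fresh = 5L, n_wi = 5L, noise_sd = 0.01,
                          seed = 14L)
  ds <- generate_study(cfg)
  model <- fit_mpls(ds, R = 3L)
  expect_gte(model$r2y_cum, 0.99)
  is_wi <- ds$labels == "wi"
  s1 <- model$scores[, 1L] * sign(model$y_loadings[2L, 1L])
  expect_gt(min(s1[is_wi]), max(s1[!is_wi]))
  preds <- predict_dataset(model, ds)
  expect_identical(preds$predicted_class, ds$labels)
})

test_that("single-class input and excessive R are rejected", {
  ds <- generate_fresh(generator_config(n_fresh = 6L, seed = 2L))
  expect_error(fit_mpls(ds, R = 2L), "per class")
  mixed <- default_study(seed = 2L)
  expect_error(fit_mpls(mixed, R = 99L), "rank")
})

test_that("B-matrix and sequential score-path predictions agree", {
  ds <- default_study(seed = 15L)
  model <- fit_mpls(ds, R = 3L)
  set.seed(55)
  b <- get_batch(ds, 2L) + matrix(rnorm(150, sd = 0.2), 25L, 6L)
  q <- predict_quality(model, b)
  # independent route: NIPALS recursion with deflation
  x <- as.vector(apply_scaler(b, model$scaler))
  yhat2 <- model$y_mean
  for (r in seq_len(model$R)) {
    t_r <- sum(x * model$weights[, r])
    x <- x - t_r * model$x_loadings[, r]
    yhat2 <- yhat2 + t_r * model$y_loadings[, r]
  }
  expect_equal(q$yhat, yhat2, tolerance = 1e-8)
  expect_equal(sum(q$normalized_yhat), 1, tolerance = 1e-12)
  expect_identical(q$predicted_class,
                   model$class_order[which.max(q$normalized_yhat)])
})

test_that("X residuals are orthogonal to all retained scores", {
  model <- fit_mpls(default_study(seed = 16L), R = 3L)
  expect_lt(max(abs(crossprod(model$scores, model$x_residuals))), 1e-8)
})

test_that("the 0.5 boundary classifies as warm-ischemic", {
  model <- fit_mpls(default_study(seed = 17L), R = 2L)
  # force a tie through the internal rule by symmetry of normalized yhat
  fake <- model
  fake$coefficients[] <- 0
  fake$y_mean <- c(fresh = 0.5, wi = 0.5)
  q <- predict_quality(fake, matrix(1, 25L, 6L) * model$scaler$means)
  expect_identical(q$predicted_class, "wi")
  expect_equal(q$quality, 0.5)
})

test_that("VIP satisfies its normalization identity and ranks the signature", {
  model <- fit_mpls(default_study(seed = 1L), R = 3L)
  v <- vip(model)
  expect_equal(mean(v$by_column$vip^2), 1, tolerance = 1e-8)
  expect_true(all(v$by_column$vip >= 0))
  for (met in c("Albumin", "Arginine", "Glutamate", "Ornithine",
                "Tyrosine"))
    expect_gt(v$by_metabolite[[met]], 1)
})

test_that("uniform weights give unit VIP everywhere", {
  # X whose scaled columns are identical: all weights equal in magnitude
  set.seed(3)
  col <- rnorm(6L)
  vals <- array(rep(col, 4L), c(6L, 2L, 2L))
  ds <- batch_dataset(vals, rep(c("fresh", "wi"), 3L))
  model <- suppressWarnings(fit_mpls(ds, R = 1L))
  v <- vip(model)
  expect_equal(unname(v$by_column$vip), rep(1, 4L), tolerance = 1e-8)
})

test_that("hourly online prediction is consistent and accurate from hour 3", {
  ds <- default_study(seed = 18L)
  train <- subset_batches(ds, c(1:5, 11:15))
  test <- subset_batches(ds, c(6:10, 16L))
  models <- fit_hourly_mpls(train, R = 3L)
  # k = K equals the full-model offline prediction
  b <- get_batch(test, 1L)
  qK <- online_predict(models, b, 6L)
  q_full <- predict_quality(models[[6L]], b)
  expect_equal(qK$quality, q_full$quality, tolerance = 1e-12)
  # separable synthetic data: correct classification from hour 3 on
  for (i in seq_len(n_batches(test))) {
    for (k in 3:6) {
      q <- online_predict(models, get_batch(test, i), k)
      expect_identical(q$predicted_class, test$labels[i])
    }
  }
  # zero-deviation fill strategy runs and agrees at k = K
  qz <- online_predict(models, b, 6L, strategy = "zero_fill")
  expect_equal(qz$quality, q_full$quality, tolerance = 1e-12)
  expect_error(online_predict(models, b, 9L), "model")
})

test_that("a zero-effect perturbation leaves prediction at chance", {
  cfg <- generator_config(n_fresh = 5L, n_wi = 5L, seed = 20L)
  cfg$wi_perturbation[] <- 0
  train <- generate_study(cfg)
  model <- fit_mpls(train, R = 3L)
  cfg_test <- generator_config(n_fresh = 100L, n_wi = 100L, seed = 21L)
  cfg_test$wi_perturbation[] <- 0
  test <- generate_study(cfg_test)
  preds <- predict_dataset(model, test)
  acc <- mean(preds$predicted_class == test$labels)
  expect_gte(acc, 0.3)
  expect_lte(acc, 0.7)
})
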