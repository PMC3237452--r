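#' Dummy-code class labels for discriminant PLS
#'
#' Builds the I x G indicator response: for a fresh batch the row is
#' `[1, 0]`, for a warm-ischemic batch `[0, 1]` (class order fixed as
#' fresh, wi).
#'
#' @param labels Character vector with values in `class_order`.
#' @param class_order Ordered class labels (default `c("fresh", "wi")`).
#' @return List of class `dummy_response` with `matrix` (I x G, 0/1) and
#'   `class_order`.
#' @export
encode_classes <- function(labels, class_order = c("fresh", "wi")) {
  bad <- setdiff(unique(labels), class_order)
  if (length(bad)) stop("unseen label(s): ", paste(bad, collapse = ", "))
  Y <- outer(labels, class_order, `==`) * 1
  colnames(Y) <- class_order
  structure(list(matrix = Y, class_order = class_order),
            class = "dummy_response")
}

#' Fit a multiway PLS discriminant model (NIPALS)
#'
#' Autoscales the unfolded batch trajectories (X, `I x JK`), mean-centers
#' the dummy response (Y, `I x G`), and extracts R components by the
#' NIPALS algorithm with X-block and Y-block deflation. For each
#' component: `w = X'u / u'u` (normalized), `t = X w`,
#' `q = Y't / t't`, `u = Y q / q'q`, iterated until the weight change is
#' below `tol`; then `p = X't / t't`, `X <- X - t p'`, `Y <- Y - t q'`.
#' The regression coefficients are `B = W (P'W)^-1 Q'` so that
#' `yhat = x_scaled B + y_mean`.
#'
#' @param dataset A [batch_dataset()] with >= 2 batches per class.
#' @param labels Class labels; defaults to `dataset$labels`.
#' @param R Number of PLS components (default 3).
#' @param tol NIPALS convergence tolerance on the weight vector change
#'   (default 1e-10).
#' @param max_iter Iteration cap per component (default 500).
#' @return An object of class `mplsda_model` with the scaler, `weights`
#'   W, `x_loadings` P, `y_loadings` Q, `coefficients` B, `y_mean`,
#'   `scores` T, per-component explained variance in X and Y
#'   (`r2x`, `r2y`), and `class_order`.
#' @export
fit_mpls <- function(dataset, labels = dataset$labels, R = 3L,
                     tol = 1e-10, max_iter = 500L) {
  dummy <- encode_classes(labels)
  if (any(table(factor(labels, dummy$class_order)) < 2L))
    stop("need >= 2 batches per class")
  scaler <- fit_scaler(dataset)
  uf <- unfold(apply_scaler(dataset, scaler), "batchwise")
  X <- uf$matrix
  y_mean <- colMeans(dummy$matrix)
  Y <- sweep(dummy$matrix, 2L, y_mean)
  I <- nrow(X); ncolX <- ncol(X); G <- ncol(Y)
  ssx_tot <- sum(X^2); ssy_tot <- sum(Y^2)
  if (R > min(I - 1L, ncolX)) stop("R exceeds the rank of X")
  W <- matrix(0, ncolX, R); P <- matrix(0, ncolX, R)
  Q <- matrix(0, G, R); Tsc <- matrix(0, I, R)
  ssy_comp <- ssx_comp <- numeric(R)
  R_used <- 0L
  for (r in seq_len(R)) {
    if (sum(Y^2) < 1e-12 * max(ssy_tot, 1)) break # Y fully explained
    u <- Y[, which.max(colSums(Y^2))]
    w_old <- rep(0, ncolX)
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      w <- crossprod(X, u)[, 1L]
      nw <- sqrt(sum(w^2))
      if (nw < 1e-300) stop("NIPALS breakdown at component ", r)
      w <- w / nw
      t_vec <- (X %*% w)[, 1L]
      q <- crossprod(Y, t_vec)[, 1L] / sum(t_vec^2)
      u <- (Y %*% q)[, 1L] / sum(q^2)
      if (sum((w - w_old)^2) < tol^2) { converged <- TRUE; break }
      w_old <- w
    }
    if (!converged)
      stop("NIPALS did not converge for component ", r,
           " within ", max_iter, " iterations")
    p <- crossprod(X, t_vec)[, 1L] / sum(t_vec^2)
    W[, r] <- w; P[, r] <- p; Q[, r] <- q; Tsc[, r] <- t_vec
    ssx_comp[r] <- sum(t_vec^2) * sum(p^2)
    ssy_comp[r] <- sum(t_vec^2) * sum(q^2)
    X <- X - tcrossprod(t_vec, p)
    Y <- Y - tcrossprod(t_vec, q)
    R_used <- r
  }
  if (R_used == 0L) stop("no PLS component could be extracted")
  if (R_used < R)
    warning("response block exhausted after ", R_used,
            " components; requested ", R)
  keep <- seq_len(R_used)
  W <- W[, keep, drop = FALSE]; P <- P[, keep, drop = FALSE]
  Q <- Q[, keep, drop = FALSE]; Tsc <- Tsc[, keep, drop = FALSE]
  Rmat <- W %*% solve(crossprod(P, W)) # x-rotations: T = X Rmat
  B <- Rmat %*% t(Q)
  r2y_resid <- 1 - sum(Y^2) / ssy_tot
  structure(list(scaler = scaler, weights = W, x_loadings = P,
                 y_loadings = Q, rotations = Rmat, coefficients = B,
                 y_mean = y_mean, scores = Tsc, R = R_used,
                 r2x = ssx_comp[keep] / ssx_tot,
                 r2y = ssy_comp[keep] / ssy_tot,
                 r2y_cum = r2y_resid,
                 class_order = dummy$class_order,
                 J = uf$J, K = uf$K, panel = dataset$panel,
                 x_residuals = X, y_residuals = Y),
            class = "mplsda_model")
}

#' @export
print.mplsda_model <- function(x, ...) {
  cat(sprintf("<mplsda_model> R = %d (%d metabolites x %d hours)\n",
              x$R, x$J, x$K))
  cat(sprintf("  R2X = %.3f, R2Y = %.4f\n", sum(x$r2x), x$r2y_cum))
  invisible(x)
}

#' Predict the quality estimate and class of a batch
#'
#' Scales and unfolds the batch, computes `yhat = x B + y_mean`,
#' normalizes it to sum 1, and classifies by the maximum of the normalized
#' vector. The quality estimate is the normalized fresh-class score; a
#' liver is called fresh only when it exceeds 0.5, so an exact tie is
#' classified as warm-ischemic (an ambiguous organ is treated as
#' ischemic).
#'
#' @param model An `mplsda_model`.
#' @param batch A `J x K` matrix (hours must match the model's K).
#' @param batch_id Identifier stored in the result.
#' @return List of class `quality_estimate` with `yhat`,
#'   `normalized_yhat`, `quality`, `predicted_class`, `batch_id`.
#' @export
predict_quality <- function(model, batch, batch_id = "new") {
  x <- as.matrix(batch)
  if (!all(dim(x) == c(model$J, model$K)))
    stop("batch must be J x K matching the model")
  xs <- unfold_batch_vector(apply_scaler(x, model$scaler))
  yhat <- (xs %*% model$coefficients)[1L, ] + model$y_mean
  s <- sum(yhat)
  norm_y <- if (abs(s) < 1e-12) rep(1 / length(yhat), length(yhat))
            else yhat / s
  names(norm_y) <- model$class_order
  # argmax with ties (and the 0.5 boundary) resolved toward "wi"
  best <- max(norm_y)
  cand <- model$class_order[norm_y >= best - 1e-15]
  pred <- if ("wi" %in% cand) "wi" else cand[1L]
  structure(list(batch_id = batch_id, yhat = yhat,
                 normalized_yhat = norm_y,
                 quality = unname(norm_y["fresh"]),
                 predicted_class = pred),
            class = "quality_estimate")
}

#' Predict every batch of a dataset
#'
#' @param model An `mplsda_model`.
#' @param dataset A [batch_dataset()].
#' @return data.frame with one row per batch: `batch_id`, `label`,
#'   `quality`, `predicted_class`.
#' @export
predict_dataset <- function(model, dataset) {
  rows <- lapply(seq_len(n_batches(dataset)), function(i) {
    q <- predict_quality(model, get_batch(dataset, i),
                         dataset$batch_ids[i])
    data.frame(batch_id = q$batch_id, label = dataset$labels[i],
               quality = q$quality, predicted_class = q$predicted_class)
  })
  do.call(rbind, rows)
}

#' Variable importance in the projection (VIP)
#'
#' Standard VIP over the retained components:
#' `VIP_col = sqrt( JK * sum_r SSY_r w_{col,r}^2 / sum_r SSY_r )` with
#' `SSY_r` the response sum of squares explained by component r and w the
#' unit-norm NIPALS weights; the mean of the squared column VIPs is 1 by
#' construction. Per-metabolite importance aggregates the K hourly columns
#' by root mean square. Columns (variables) with VIP > 1 are the
#' influential ones.
#'
#' @param model An `mplsda_model`.
#' @return List of class `vip_vector` with `by_column` (data.frame:
#'   metabolite, hour, vip) and `by_metabolite` (named numeric).
#' @export
vip <- function(model) {
  ssy <- model$r2y # proportional to explained SSY per component
  w2 <- model$weights^2
  ncolX <- nrow(model$weights)
  v <- sqrt(ncolX * (w2 %*% ssy)[, 1L] / sum(ssy))
  mat <- matrix(v, model$J, model$K,
                dimnames = list(model$panel, paste0("h", seq_len(model$K))))
  by_col <- data.frame(metabolite = rep(model$panel, model$K),
                       hour = rep(seq_len(model$K), each = model$J),
                       vip = as.vector(mat))
  by_met <- sqrt(rowMeans(mat^2))
  structure(list(by_column = by_col, by_metabolite = by_met,
                 matrix = mat),
            class = "vip_vector")
}

#' Fit one MPLS-DA model per hour for online prediction
#'
#' Model k is fit on the truncated dataset of hours 1..k ("truncated
#' refit"), so each hour has its own scaler and loadings.
#'
#' @param dataset Training [batch_dataset()].
#' @param labels Class labels; defaults to `dataset$labels`.
#' @param R Components per model.
#' @return List of `mplsda_model`s, element k fit on hours 1..k.
#' @export
fit_hourly_mpls <- function(dataset, labels = dataset$labels, R = 3L) {
  K <- dim(dataset$values)[3L]
  lapply(seq_len(K), function(k) {
    fit_mpls(truncate_hours(dataset, k), labels, R)
  })
}

#' Online quality prediction from a partial trajectory
#'
#' Predicts the end-of-perfusion class at hour k. The default strategy
#' `"truncated"` uses the hour-k model from [fit_hourly_mpls()];
#' `"zero_fill"` uses the full-length model (last element of
#' `models_by_hour`), scaling the observed hours and padding the scaled
#' future hours with 0 (i.e. assuming the batch stays on the mean
#' trajectory).
#'
#' @param models_by_hour List of `mplsda_model`s from [fit_hourly_mpls()].
#' @param partial_batch `J x k` matrix (or wider; first k columns used).
#' @param k Current hour.
#' @param strategy `"truncated"` (default) or `"zero_fill"`.
#' @param batch_id Identifier for the result.
#' @return A `quality_estimate`.
#' @export
online_predict <- function(models_by_hour, partial_batch, k,
                           strategy = c("truncated", "zero_fill"),
                           batch_id = "new") {
  strategy <- match.arg(strategy)
  if (k < 1L || k > length(models_by_hour) ||
      is.null(models_by_hour[[k]]))
    stop("no model available for hour ", k)
  x <- as.matrix(partial_batch)[, seq_len(k), drop = FALSE]
  if (strategy == "truncated") {
    return(predict_quality(models_by_hour[[k]], x, batch_id))
  }
  model <- models_by_hour[[length(models_by_hour)]]
  xs_part <- apply_scaler(x, model$scaler)
  xs <- cbind(xs_part, matrix(0, model$J, model$K - k))
  row <- unfold_batch_vector(xs)
  yhat <- (row %*% model$coefficients)[1L, ] + model$y_mean
  s <- sum(yhat)
  norm_y <- if (abs(s) < 1e-12) rep(1 / length(yhat), length(yhat))
            else yhat / s
  names(norm_y) <- model$class_order
  best <- max(norm_y)
  cand <- model$class_order[norm_y >= best - 1e-15]
  pred <- if ("wi" %in% cand) "wi" else cand[1L]
  structure(list(batch_id = batch_id, yhat = yhat,
                 normalized_yhat = norm_y,
                 quality = unname(norm_y["fresh"]),
                 predicted_class = pred),
            class = "quality_estimate")
}
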