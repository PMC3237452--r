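#' Scaled chi-squared control limit for an SPE sample
#'
#' The SPE of in-control batches is approximated by a scaled chi-squared
#' variable g*chi2_h matched to the sample mean m and variance v of the
#' reference SPE sample: g = v / (2m), h = 2 m^2 / v. The control limit at
#' significance level alpha is `(v / 2m) * qchisq(1 - alpha, 2 m^2 / v)`.
#'
#' @param spe_sample Numeric vector of reference SPE values (length >= 3,
#'   positive variance).
#' @param alpha Significance level(s) in (0, 1).
#' @return Named numeric vector of limits, one per alpha.
#' @export
spe_limit <- function(spe_sample, alpha = c(0.05, 0.01)) {
  spe_sample <- spe_sample[is.finite(spe_sample)]
  if (length(spe_sample) < 3L) stop("need >= 3 SPE values")
  if (any(alpha <= 0 | alpha >= 1)) stop("alpha must be in (0, 1)")
  m <- mean(spe_sample)
  v <- stats::var(spe_sample)
  if (!is.finite(v) || v <= .Machine$double.eps * max(1, m^2))
    stop("degenerate SPE sample: zero variance, no limit defined")
  g <- v / (2 * m)
  h <- 2 * m^2 / v
  lim <- g * stats::qchisq(1 - alpha, df = h)
  names(lim) <- paste0("alpha_", alpha)
  lim
}

# Internal: limits that degrade to NA instead of erroring, for degenerate
# training SPE samples (e.g. the completeness limit R = min(I-1, JK)).
spe_limit_or_na <- function(spe_sample, alpha) {
  tryCatch(spe_limit(spe_sample, alpha),
           error = function(e) {
             out <- rep(NA_real_, length(alpha))
             names(out) <- paste0("alpha_", alpha)
             out
           })
}

# Internal: truncated-loading least-squares scores for hours 1..k of a
# scaled, unfolded row vector x_k (1 x J*k). Pseudo-inverse handles rank
# deficiency of the truncated loading block.
truncated_scores <- function(P, J, x_k, k) {
  Pk <- P[seq_len(J * k), , drop = FALSE]
  x_k %*% t(MASS::ginv(Pk))
}

# Internal: leading-R right principal directions of a centered/scaled
# matrix, sign-fixed so the largest-|entry| of each column is positive.
principal_directions <- function(X, R) {
  ev <- eigen(crossprod(X), symmetric = TRUE)
  lambda <- pmax(ev$values, 0)
  tol <- max(dim(X)) * .Machine$double.eps * max(lambda, 0)
  rank <- sum(lambda > max(tol, 0))
  if (rank == 0L)
    stop("degenerate training data: all singular values are zero ",
         "(identical batches?)")
  if (R > rank)
    stop("R = ", R, " exceeds the rank (", rank, ") of the scaled data")
  P <- ev$vectors[, seq_len(R), drop = FALSE]
  for (r in seq_len(R)) {
    i_max <- which.max(abs(P[, r]))
    if (P[i_max, r] < 0) P[, r] <- -P[, r]
  }
  list(P = P, lambda = lambda, rank = rank)
}

# Internal: offline SPE, per-hour online SPE and the full residual row for
# one scaled, unfolded batch row x (1 x JK) against loadings P.
spe_components_row <- function(P, J, K, x) {
  e <- x - (x %*% P) %*% t(P)
  spe_on <- numeric(K)
  for (k in seq_len(K)) {
    cols <- seq_len(J * k)
    Pk <- P[cols, , drop = FALSE]
    tk <- x[, cols, drop = FALSE] %*% t(MASS::ginv(Pk))
    ek <- x[, cols, drop = FALSE] - tk %*% t(Pk)
    spe_on[k] <- sum(ek[1L, (k - 1L) * J + seq_len(J)]^2)
  }
  list(residual = e, spe_offline = sum(e^2), spe_online = spe_on)
}

#' Fit the multiway PCA normal-operation model
#'
#' Autoscales the training batches per (metabolite, hour) column, unfolds
#' batch-wise to `I x JK`, and takes the R leading right singular
#' directions as loadings. The model stores the scaler, loadings, training
#' scores, explained variance, the SPE reference samples (offline, and
#' per-hour online using the same truncated-loading projection applied to
#' new partial batches) and their scaled chi-squared control limits.
#'
#' With `limit_method = "loo"` (the default) the reference SPE samples and
#' the contribution reference band are computed leave-one-out: each
#' training batch's SPE and residuals come from a model (scaler and
#' loadings) refit without that batch. In-sample residuals understate the
#' prediction error of genuinely new batches, so in-sample limits run
#' anti-conservative; the leave-one-out reference restores the nominal
#' false-alarm rate. `"insample"` uses the plain training residuals. The
#' fit falls back to `"insample"` (with a message) when leave-one-out
#' refits are infeasible, e.g. R equal to the leave-one-out rank.
#'
#' @param training A [batch_dataset()] of normal (fresh) batches,
#'   >= 2 batches and > R effective rank.
#' @param R Number of principal components (default 3).
#' @param alpha Significance levels for control limits.
#' @param index_log_base Log base of the ischemia index (default 10).
#' @param index_threshold Ischemia-index alarm threshold on
#'   `log(SPE)` (default 1.35).
#' @param limit_method `"loo"` (default) or `"insample"`; see Details.
#' @return An object of class `mpca_model`.
#' @export
fit_mpca <- function(training, R = 3L, alpha = c(0.05, 0.01),
                     index_log_base = 10, index_threshold = 1.35,
                     limit_method = c("loo", "insample")) {
  limit_method <- match.arg(limit_method)
  if (R < 1L) stop("R must be >= 1")
  if (n_batches(training) < 2L) stop("need >= 2 training batches")
  scaler <- fit_scaler(training)
  uf <- unfold(apply_scaler(training, scaler), "batchwise")
  X <- uf$matrix
  I <- nrow(X); J <- uf$J; K <- uf$K
  pd <- principal_directions(X, R)
  P <- pd$P
  Tsc <- X %*% P
  expl <- pd$lambda / sum(pd$lambda)
  E <- X - Tsc %*% t(P)
  spe_off <- rowSums(E^2)
  spe_on <- matrix(NA_real_, I, K)
  for (k in seq_len(K)) {
    cols <- seq_len(J * k)
    Pk <- P[cols, , drop = FALSE]
    Hk <- t(MASS::ginv(Pk))
    Tk <- X[, cols, drop = FALSE] %*% Hk
    Ek <- X[, cols, drop = FALSE] - Tk %*% t(Pk)
    spe_on[, k] <- rowSums(Ek[, (k - 1L) * J + seq_len(J), drop = FALSE]^2)
  }
  # reference samples for limits and contribution bands
  ref <- list(E = E, off = spe_off, on = spe_on, method = "insample")
  if (limit_method == "loo" && I >= 4L) {
    Xraw <- unfold(training, "batchwise")$matrix
    loo <- tryCatch({
      E_loo <- matrix(NA_real_, I, J * K)
      off_loo <- numeric(I)
      on_loo <- matrix(NA_real_, I, K)
      for (i in seq_len(I)) {
        Xi <- Xraw[-i, , drop = FALSE]
        mu_i <- colMeans(Xi)
        sd_i <- sqrt(colSums(sweep(Xi, 2L, mu_i)^2) / (I - 2L))
        degen <- sd_i <= 0 | !is.finite(sd_i)
        sd_i[degen] <- 1
        Xs_i <- sweep(sweep(Xi, 2L, mu_i), 2L, sd_i, `/`)
        P_i <- principal_directions(Xs_i, R)$P
        x_i <- matrix((Xraw[i, ] - mu_i) / sd_i, nrow = 1L)
        sc <- spe_components_row(P_i, J, K, x_i)
        E_loo[i, ] <- sc$residual
        off_loo[i] <- sc$spe_offline
        on_loo[i, ] <- sc$spe_online
      }
      list(E = E_loo, off = off_loo, on = on_loo, method = "loo")
    }, error = function(e) NULL)
    if (is.null(loo)) {
      message("leave-one-out reference infeasible; ",
              "falling back to in-sample limits")
    } else ref <- loo
  } else if (limit_method == "loo") {
    message("too few batches for leave-one-out limits; using in-sample")
  }
  lim_on <- sapply(seq_len(K),
                   function(k) spe_limit_or_na(ref$on[, k], alpha))
  lim_on <- matrix(lim_on, nrow = length(alpha), ncol = K,
                   dimnames = list(paste0("alpha_", alpha),
                                   paste0("h", seq_len(K))))
  structure(list(scaler = scaler, loadings = P, scores = Tsc, R = R,
                 explained_variance = expl[seq_len(pd$rank)],
                 singular_values = sqrt(pd$lambda),
                 residuals_train = E,
                 residuals_ref = ref$E,
                 limit_method = ref$method,
                 spe_train_offline = spe_off,
                 spe_train_online = spe_on,
                 spe_ref_offline = ref$off,
                 spe_ref_online = ref$on,
                 limits_offline = spe_limit_or_na(ref$off, alpha),
                 limits_online = lim_on,
                 alpha = alpha, J = J, K = K, I_train = I,
                 panel = training$panel,
                 index_log_base = index_log_base,
                 index_threshold = index_threshold),
            class = "mpca_model")
}

#' @export
print.mpca_model <- function(x, ...) {
  cat(sprintf("<mpca_model> R = %d on %d batches (%d metabolites x %d hours)\n",
              x$R, x$I_train, x$J, x$K))
  cat(sprintf("  cumulative explained variance (R comps): %.1f%%\n",
              100 * sum(x$explained_variance[seq_len(x$R)])))
  invisible(x)
}

#' Project a new batch onto the MPCA model
#'
#' Scales the batch with the training scaler, unfolds it to a `1 x JK` row
#' and computes scores `t = x P` and residuals `e = x - t P'`.
#'
#' @param model An `mpca_model`.
#' @param batch A `J x K` matrix (or a [batch_dataset()] with one batch).
#' @return List with `scores` (`1 x R`) and `residuals` (`1 x JK`, in the
#'   batchwise column order).
#' @export
project_batch <- function(model, batch) {
  if (inherits(batch, "batch_dataset")) batch <- get_batch(batch, 1L)
  batch <- as.matrix(batch)
  if (!all(dim(batch) == c(model$J, model$K)))
    stop("batch must be J x K (full trajectory)")
  x <- unfold_batch_vector(apply_scaler(batch, model$scaler))
  t_new <- x %*% model$loadings
  e_new <- x - t_new %*% t(model$loadings)
  list(scores = t_new, residuals = e_new)
}

# Internal: scale + unfold a whole dataset against a model.
scaled_unfolded <- function(model, dataset) {
  if (!all(dim(dataset$values)[2:3] == c(model$J, model$K)))
    stop("dataset shape does not match model")
  unfold(apply_scaler(dataset, model$scaler), "batchwise")$matrix
}

#' Offline SPE (Q-statistic) of complete batches
#'
#' The squared prediction error `SPE = sum(e^2)` over all JK residual
#' entries of a completed batch, with the model's offline control limits
#' and the log ischemia index attached.
#'
#' @param model An `mpca_model`.
#' @param data A `J x K` batch matrix or a [batch_dataset()].
#' @return An object of class `spe_trace` (mode `"offline"`): data.frame
#'   with columns `batch_id`, `spe`, `log_index`, per-alpha exceedance
#'   flags, and `index_flag` (`log_index > threshold`).
#' @export
spe_offline <- function(model, data) {
  if (!inherits(data, "batch_dataset")) {
    data <- batch_dataset(array(as.matrix(data),
                                c(1L, model$J, model$K)),
                          "unknown", model$panel, "new")
  }
  X <- scaled_unfolded(model, data)
  E <- X - (X %*% model$loadings) %*% t(model$loadings)
  spe <- rowSums(E^2)
  log_index <- log(pmax(spe, .Machine$double.xmin),
                   base = model$index_log_base)
  out <- data.frame(batch_id = data$batch_ids, spe = spe,
                    log_index = log_index, row.names = NULL)
  for (a in seq_along(model$alpha)) {
    out[[paste0("exceeds_", names(model$limits_offline)[a])]] <-
      spe > model$limits_offline[a]
  }
  out$index_flag <- log_index > model$index_threshold
  structure(out, mode = "offline", limits = model$limits_offline,
            class = c("spe_trace", "data.frame"))
}

#' Online scores from a partial trajectory
#'
#' At hour k only the first `J*k` rows of the loading matrix are available;
#' scores are the least-squares solution on that truncated block (via
#' pseudo-inverse, robust to rank deficiency). At k = K this reduces to
#' the ordinary projection.
#'
#' @param model An `mpca_model`.
#' @param partial_batch A `J x k` matrix of hours 1..k.
#' @param k Current hour, `1 <= k <= K`.
#' @return List with `scores` (`1 x R`) and `residuals` (`1 x J*k`).
#' @export
online_scores <- function(model, partial_batch, k) {
  if (k < 1L || k > model$K) stop("k out of range")
  x <- as.matrix(partial_batch)
  if (nrow(x) != model$J || ncol(x) != k)
    stop("partial batch must be J x k")
  xs <- unfold_batch_vector(apply_scaler(x, model$scaler))
  t_new <- truncated_scores(model$loadings, model$J, xs, k)
  Pk <- model$loadings[seq_len(model$J * k), , drop = FALSE]
  e <- xs - t_new %*% t(Pk)
  list(scores = t_new, residuals = e)
}

#' Online SPE at hour k
#'
#' The per-hour monitoring statistic: by default the instantaneous sum of
#' the J squared residuals of hour k (`mode = "instantaneous"`), or the
#' cumulative sum over hours 1..k (`mode = "cumulative"`). The per-hour
#' scaled chi-squared limit, log ischemia index and `> threshold` flag are
#' attached.
#'
#' @param model An `mpca_model`.
#' @param partial_batch `J x k` matrix of hours 1..k (or a full `J x K`
#'   batch, of which the first k hours are used).
#' @param k Hour(s) at which to evaluate; defaults to all hours available
#'   in `partial_batch`.
#' @param mode `"instantaneous"` (default) or `"cumulative"`.
#' @param batch_id Identifier for the output rows.
#' @return An `spe_trace` (mode `"online"`): data.frame with columns
#'   `batch_id`, `hour`, `spe`, `log_index`, per-alpha flags, `index_flag`.
#' @export
spe_online <- function(model, partial_batch, k = NULL,
                       mode = c("instantaneous", "cumulative"),
                       batch_id = "new") {
  mode <- match.arg(mode)
  x <- as.matrix(partial_batch)
  if (is.null(k)) k <- seq_len(ncol(x))
  if (any(k < 1L | k > model$K)) stop("k out of range")
  rows <- lapply(k, function(kk) {
    if (ncol(x) < kk) stop("partial batch has fewer than k hours")
    os <- online_scores(model, x[, seq_len(kk), drop = FALSE], kk)
    e <- os$residuals
    spe_k <- if (mode == "instantaneous") {
      hour_cols <- (kk - 1L) * model$J + seq_len(model$J)
      sum(e[1L, hour_cols]^2)
    } else sum(e^2)
    spe_k
  })
  spe <- unlist(rows)
  log_index <- log(pmax(spe, .Machine$double.xmin),
                   base = model$index_log_base)
  out <- data.frame(batch_id = batch_id, hour = k, spe = spe,
                    log_index = log_index, row.names = NULL)
  for (a in seq_along(model$alpha)) {
    lim <- model$limits_online[a, k]
    out[[paste0("exceeds_", rownames(model$limits_online)[a])]] <- spe > lim
  }
  out$index_flag <- log_index > model$index_threshold
  structure(out, mode = "online", limits = model$limits_online,
            class = c("spe_trace", "data.frame"))
}

#' Online SPE traces for every batch of a dataset
#'
#' @param model An `mpca_model`.
#' @param dataset A [batch_dataset()] of full batches.
#' @param mode Passed to [spe_online()].
#' @return An `spe_trace` data.frame with one row per batch and hour.
#' @export
spe_online_dataset <- function(model, dataset,
                               mode = c("instantaneous", "cumulative")) {
  mode <- match.arg(mode)
  out <- do.call(rbind, lapply(seq_len(n_batches(dataset)), function(i) {
    spe_online(model, get_batch(dataset, i), mode = mode,
               batch_id = dataset$batch_ids[i])
  }))
  structure(out, mode = "online", limits = model$limits_online,
            class = c("spe_trace", "data.frame"))
}

#' Per-variable contributions to the SPE
#'
#' Decomposes a batch's residual into per-(metabolite, hour) terms: the
#' squared contributions `e_jk^2` (non-negative, summing exactly to the
#' offline SPE) and the signed normalized errors `e_jk / s_jk` with `s_jk`
#' the training sd of metabolite j at hour k, whose sign says whether the
#' metabolite ran above or below the fresh reference.
#'
#' @param model An `mpca_model`.
#' @param batch A `J x K` matrix.
#' @param batch_id Identifier stored in the result.
#' @return An object of class `contribution_table`: list with `squared`
#'   and `normalized` (`J x K` matrices), `spe`, `batch_id`.
#' @export
contributions <- function(model, batch, batch_id = "new") {
  pr <- project_batch(model, batch)
  e <- matrix(pr$residuals[1L, ], model$J, model$K,
              dimnames = list(model$panel, paste0("h", seq_len(model$K))))
  structure(list(squared = e^2,
                 normalized = e / model$scaler$sds,
                 spe = sum(e^2), batch_id = batch_id),
            class = "contribution_table")
}

# Internal: reference contribution tables of the training batches (from
# the model's reference residuals, leave-one-out when available), as
# I x J x K arrays per statistic.
training_contribution_reference <- function(model) {
  I <- model$I_train
  sq <- array(NA_real_, c(I, model$J, model$K))
  nm <- array(NA_real_, c(I, model$J, model$K))
  for (i in seq_len(I)) {
    e <- matrix(model$residuals_ref[i, ], model$J, model$K)
    sq[i, , ] <- e^2
    nm[i, , ] <- e / model$scaler$sds
  }
  list(squared = sq, normalized = nm)
}

#' Flag metabolites whose contributions exceed the fresh 3-sigma band
#'
#' A metabolite is flagged at hour k when its contribution falls outside
#' the normal band derived from the fresh training batches at that
#' (metabolite, hour). The default statistic is the signed normalized
#' error with a two-sided `mean +/- n_sigma * sd` band; the squared
#' contribution with a one-sided `mean + n_sigma * sd` limit is available
#' as `statistic = "squared"`.
#'
#' @param model An `mpca_model` fit on >= 3 batches.
#' @param table A `contribution_table` from [contributions()].
#' @param n_sigma Width of the normal band (default 3).
#' @param statistic `"normalized"` (default) or `"squared"`.
#' @return data.frame with columns `metabolite`, `hour`, `value`,
#'   `lower`, `upper` for every flagged (metabolite, hour).
#' @export
flag_contributors <- function(model, table, n_sigma = 3,
                              statistic = c("normalized", "squared")) {
  statistic <- match.arg(statistic)
  if (model$I_train < 3L) stop("need >= 3 training batches for the band")
  ref <- training_contribution_reference(model)[[statistic]]
  mu <- apply(ref, c(2L, 3L), mean)
  sg <- apply(ref, c(2L, 3L), stats::sd)
  val <- table[[statistic]]
  if (statistic == "normalized") {
    lower <- mu - n_sigma * sg
    upper <- mu + n_sigma * sg
    hit <- val < lower | val > upper
  } else {
    lower <- matrix(-Inf, model$J, model$K)
    upper <- mu + n_sigma * sg
    hit <- val > upper
  }
  idx <- which(hit, arr.ind = TRUE)
  data.frame(metabolite = model$panel[idx[, 1L]],
             hour = as.integer(idx[, 2L]),
             value = val[idx],
             lower = lower[idx], upper = upper[idx],
             row.names = NULL)[order(idx[, 2L], idx[, 1L]), , drop = FALSE]
}

#' Hotelling confidence ellipse in score space
#'
#' Two-component confidence ellipse of the training scores: with I
#' training batches and per-component score variances s^2, the boundary is
#' `t_a^2/s_a^2 + t_b^2/s_b^2 = (2 (I^2 - 1) / (I (I - 2))) F_{2, I-2, 1-alpha}`,
#' centered at the origin.
#'
#' @param model An `mpca_model` with R >= 2.
#' @param pc_pair Integer pair of component indices (default c(1, 2)).
#' @param alpha Significance level(s).
#' @return List of class `ellipse_spec` with `pc_pair`, `score_sd`, and a
#'   per-alpha matrix of `semi_axes`.
#' @export
score_ellipse <- function(model, pc_pair = c(1L, 2L),
                          alpha = c(0.05, 0.01)) {
  if (model$R < 2L) stop("need R >= 2 for a score ellipse")
  if (length(pc_pair) != 2L || any(pc_pair > model$R))
    stop("pc_pair must index two fitted components")
  I <- model$I_train
  if (I < 3L) stop("need >= 3 training batches")
  s <- apply(model$scores[, pc_pair, drop = FALSE], 2L, stats::sd)
  t2lim <- (2 * (I^2 - 1) / (I * (I - 2))) * stats::qf(1 - alpha, 2, I - 2)
  semi <- t(vapply(t2lim, function(l) s * sqrt(l), numeric(2L)))
  dimnames(semi) <- list(paste0("alpha_", alpha), paste0("pc", pc_pair))
  structure(list(pc_pair = pc_pair, score_sd = s, t2_limits = t2lim,
                 alpha = alpha, semi_axes = semi, center = c(0, 0)),
            class = "ellipse_spec")
}

#' Detect outlier batches in score space
#'
#' Projects every batch of `dataset` onto the model and flags those whose
#' score pair falls outside the Hotelling confidence region at level
#' `alpha` (default 99%). The per-batch test is jackknifed: each batch is
#' judged against score standard deviations estimated from the other
#' batches, so a single gross outlier cannot mask itself by inflating the
#' score variance it is tested against. Flagged ids are meant to be
#' excluded before the final normal-operation model is refit.
#'
#' @param model An `mpca_model` with R >= 2.
#' @param dataset A [batch_dataset()] with >= 5 batches.
#' @param alpha Significance level of the rejection region (default 0.01).
#' @param pc_pair Component pair (default c(1, 2)).
#' @return Character vector of outlier batch ids (possibly empty).
#' @export
detect_outlier_batches <- function(model, dataset, alpha = 0.01,
                                   pc_pair = c(1L, 2L)) {
  if (model$R < 2L) stop("need R >= 2 for score-space screening")
  X <- scaled_unfolded(model, dataset)
  Tsc <- X %*% model$loadings[, pc_pair, drop = FALSE]
  n <- nrow(Tsc)
  if (n < 5L) stop("need >= 5 batches to screen for outliers")
  m <- n - 1L # each batch is tested against the other n-1
  lim <- (2 * (m^2 - 1) / (m * (m - 2))) * stats::qf(1 - alpha, 2, m - 2)
  t2 <- vapply(seq_len(n), function(i) {
    s <- apply(Tsc[-i, , drop = FALSE], 2L, stats::sd)
    s[s <= 0] <- Inf
    sum((Tsc[i, ] / s)^2)
  }, numeric(1L))
  dataset$batch_ids[t2 > lim]
}

#' Screen a mixed dataset for outliers and return the cleaned set
#'
#' Convenience wrapper for the pre-modeling screen: fits a provisional
#' MPCA model on all batches, rejects batches outside the 99% score
#' ellipse, and returns the cleaned dataset plus the excluded ids.
#'
#' @param dataset A [batch_dataset()].
#' @param R Components for the screening model.
#' @param alpha Rejection level (default 0.01).
#' @return List with `dataset` (cleaned) and `excluded` (ids).
#' @export
screen_outliers <- function(dataset, R = 3L, alpha = 0.01) {
  model <- fit_mpca(dataset, R = R)
  out <- detect_outlier_batches(model, dataset, alpha = alpha)
  keep <- !(dataset$batch_ids %in% out)
  list(dataset = subset_batches(dataset, keep), excluded = out)
}
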