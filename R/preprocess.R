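#' Replace invalid cells by the fresh mean trajectory
#'
#' Assay failures show up as negative or non-finite concentrations. Each
#' such cell is replaced by the training-reference mean trajectory value at
#' its (metabolite, hour); all other cells are untouched.
#'
#' @param dataset A [batch_dataset()] to repair.
#' @param training_reference Either a `J x K` matrix of reference mean
#'   trajectories or a [batch_dataset()] of fresh training batches from
#'   which [mean_trajectory()] is taken.
#' @return The repaired [batch_dataset()], with attribute `n_replaced`
#'   (count of replaced cells).
#' @export
replace_invalid <- function(dataset, training_reference) {
  ref <- if (inherits(training_reference, "batch_dataset"))
    mean_trajectory(training_reference) else as.matrix(training_reference)
  d <- dim(dataset$values)
  if (!all(dim(ref) == d[2:3]))
    stop("training_reference must be J x K")
  if (any(!is.finite(ref)))
    stop("reference mean trajectory contains invalid values; ",
         "cannot repair against it")
  vals <- dataset$values
  bad <- !is.finite(vals) | vals < 0
  n_rep <- sum(bad)
  if (n_rep > 0L) {
    idx <- which(bad, arr.ind = TRUE)
    vals[bad] <- ref[idx[, 2:3, drop = FALSE]]
  }
  out <- batch_dataset(vals, dataset$labels, dataset$panel,
                       dataset$batch_ids)
  attr(out, "n_replaced") <- n_rep
  out
}

#' Fit per-(metabolite, hour) autoscaling parameters
#'
#' Means and standard deviations are computed over the batch dimension for
#' each of the J*K trajectory columns, the standard preprocessing for
#' batch-wise multiway models: every column of the unfolded matrix is
#' mean-centered and scaled to unit variance. Zero-variance columns get
#' sd = 1 and are flagged as degenerate so downstream division is safe.
#'
#' @param training A [batch_dataset()] with at least 2 batches.
#' @return An object of class `scaler_params`: list with `means`, `sds`
#'   (`J x K` matrices) and `degenerate` (logical `J x K`).
#' @export
fit_scaler <- function(training) {
  if (n_batches(training) < 2L)
    stop("need >= 2 training batches to estimate column sds")
  means <- apply(training$values, c(2L, 3L), mean)
  sds <- apply(training$values, c(2L, 3L), stats::sd)
  degenerate <- sds <= 0 | !is.finite(sds)
  sds[degenerate] <- 1
  structure(list(means = means, sds = sds, degenerate = degenerate,
                 panel = training$panel),
            class = "scaler_params")
}

#' Apply (or invert) autoscaling
#'
#' Scales `(x - mean) / sd` per (metabolite, hour) column. Accepts a full
#' [batch_dataset()], or a single `J x k` batch matrix with `k <= K`
#' (partial trajectories, for online monitoring, use the first k columns of
#' the scaler).
#'
#' @param data A [batch_dataset()] or numeric `J x k` matrix.
#' @param params A `scaler_params` object from [fit_scaler()].
#' @param invert If `TRUE`, applies the inverse transform `x * sd + mean`.
#' @return Object of the same shape as `data`.
#' @export
apply_scaler <- function(data, params, invert = FALSE) {
  K <- ncol(params$means)
  if (inherits(data, "batch_dataset")) {
    if (!all(dim(data$values)[2:3] == dim(params$means)))
      stop("dataset shape does not match scaler")
    vals <- data$values
    if (invert) {
      vals <- sweep(sweep(vals, c(2L, 3L), params$sds, `*`),
                    c(2L, 3L), params$means, `+`)
    } else {
      vals <- sweep(sweep(vals, c(2L, 3L), params$means, `-`),
                    c(2L, 3L), params$sds, `/`)
    }
    return(batch_dataset(vals, data$labels, data$panel, data$batch_ids))
  }
  x <- as.matrix(data)
  k <- ncol(x)
  if (nrow(x) != nrow(params$means) || k > K)
    stop("batch shape does not match scaler")
  m <- params$means[, seq_len(k), drop = FALSE]
  s <- params$sds[, seq_len(k), drop = FALSE]
  if (invert) x * s + m else (x - m) / s
}

#' Unfold a three-way dataset into a matrix
#'
#' Batch-wise unfolding preserves the batch direction and places the J
#' metabolite measurements of each hour side by side: row i is
#' `[x_i(.,1), x_i(.,2), ..., x_i(.,K)]`, giving an `I x JK` matrix whose
#' column `(k-1)*J + j` holds metabolite j at hour k. Variable-wise
#' unfolding preserves the metabolite direction, stacking hour-profiles
#' batch-major into an `IK x J` matrix (row `(i-1)*K + k`).
#'
#' @param dataset A [batch_dataset()].
#' @param direction `"batchwise"` (default) or `"variablewise"`.
#' @return An object of class `unfolded_data`: list with `matrix`,
#'   `direction`, `column_index` (for batchwise: data.frame mapping column
#'   to metabolite and hour) and the source dims `I`, `J`, `K`.
#' @export
unfold <- function(dataset, direction = c("batchwise", "variablewise")) {
  direction <- match.arg(direction)
  d <- dim(dataset$values); I <- d[1L]; J <- d[2L]; K <- d[3L]
  if (direction == "batchwise") {
    m <- dataset$values
    dim(m) <- c(I, J * K) # column order: j fastest, then k
    ci <- data.frame(column = seq_len(J * K),
                     metabolite_index = rep(seq_len(J), K),
                     metabolite = rep(dataset$panel, K),
                     hour = rep(seq_len(K), each = J))
    colnames(m) <- paste0(ci$metabolite, ".h", ci$hour)
    rownames(m) <- dataset$batch_ids
  } else {
    a <- aperm(dataset$values, c(3L, 1L, 2L)) # K x I x J
    m <- a
    dim(m) <- c(K * I, J) # row order: k fastest within batch i
    colnames(m) <- dataset$panel
    rownames(m) <- paste0(rep(dataset$batch_ids, each = K), ".h",
                          rep(seq_len(K), I))
    ci <- data.frame(row = seq_len(I * K),
                     batch = rep(dataset$batch_ids, each = K),
                     hour = rep(seq_len(K), I))
  }
  structure(list(matrix = m, direction = direction, column_index = ci,
                 I = I, J = J, K = K, panel = dataset$panel,
                 batch_ids = dataset$batch_ids, labels = dataset$labels),
            class = "unfolded_data")
}

#' Refold an unfolded matrix back into a dataset
#'
#' Exact inverse of [unfold()] for both directions.
#'
#' @param unfolded An `unfolded_data` object (its `matrix` may have been
#'   modified, but not reshaped).
#' @return A [batch_dataset()].
#' @export
refold <- function(unfolded) {
  I <- unfolded$I; J <- unfolded$J; K <- unfolded$K
  m <- unfolded$matrix
  if (unfolded$direction == "batchwise") {
    if (!all(dim(m) == c(I, J * K))) stop("matrix shape changed")
    vals <- m
    dim(vals) <- c(I, J, K)
  } else {
    if (!all(dim(m) == c(I * K, J))) stop("matrix shape changed")
    a <- m
    dim(a) <- c(K, I, J)
    vals <- aperm(a, c(2L, 3L, 1L))
  }
  batch_dataset(vals, unfolded$labels, unfolded$panel, unfolded$batch_ids)
}

# Unfold a single J x k batch matrix into a 1 x (J*k) row vector under the
# batchwise column order (j fastest within each hour block).
unfold_batch_vector <- function(batch) {
  x <- as.matrix(batch)
  matrix(as.vector(x), nrow = 1L)
}
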