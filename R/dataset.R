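#' The 25-metabolite perfusate panel
#'
#' Ordered identifiers of the metabolites assayed hourly in the liver
#' perfusate: 18 amino acids, ammonia, urea, glucose, lactate, albumin and
#' acetoacetate (ACAC). The index positions are fixed (e.g. #3 Albumin,
#' #5 Arginine, #9 Glutamate, #14 Lactate, #18 Ornithine, #23 Tyrosine) and
#' every dataset in the package carries its metabolite dimension in this
#' order.
#'
#' @return Character vector of length 25.
#' @export
#' @examples
#' default_panel()[c(3, 5, 18)]
default_panel <- function() {
  c("ACAC", "Alanine", "Albumin", "Ammonia", "Arginine",
    "Asparagine", "Aspartate", "Glucose", "Glutamate", "Glutamine",
    "Glycine", "Histidine", "Isoleucine", "Lactate", "Leucine",
    "Lysine", "Methionine", "Ornithine", "Phenylalanine", "Proline",
    "Serine", "Threonine", "Tyrosine", "Urea", "Valine")
}

#' Construct a perfusion batch dataset
#'
#' A `batch_dataset` is the universal container of the package: a
#' three-way array of I perfusion batches x J metabolites x K hourly time
#' points, plus a class label per batch (`"fresh"`, `"wi"` for warm
#' ischemic, or `"unknown"`).
#'
#' @param values Numeric array `I x J x K` (batch, metabolite, hour).
#' @param labels Character vector of length I.
#' @param panel Character vector of J metabolite names; defaults to
#'   [default_panel()] when J = 25.
#' @param batch_ids Optional character vector of length I; generated when
#'   missing.
#' @return An object of class `batch_dataset` with elements `values`,
#'   `labels`, `panel`, `batch_ids`.
#' @export
batch_dataset <- function(values, labels, panel = NULL, batch_ids = NULL) {
  if (length(dim(values)) != 3L)
    stop("`values` must be a 3-way array (batch x metabolite x hour)")
  I <- dim(values)[1L]; J <- dim(values)[2L]; K <- dim(values)[3L]
  if (is.null(panel)) {
    if (J == 25L) panel <- default_panel()
    else panel <- paste0("M", seq_len(J))
  }
  if (length(panel) != J) stop("panel length does not match metabolite dim")
  if (anyDuplicated(panel)) stop("panel names must be unique")
  if (length(labels) != I) stop("need one label per batch")
  labels <- as.character(labels)
  bad <- setdiff(unique(labels), c("fresh", "wi", "unknown"))
  if (length(bad))
    stop("unknown labels: ", paste(bad, collapse = ", "))
  if (is.null(batch_ids)) batch_ids <- sprintf("B%02d", seq_len(I))
  if (anyDuplicated(batch_ids)) stop("batch_ids must be unique")
  dimnames(values) <- list(batch_ids, panel, paste0("h", seq_len(K)))
  structure(list(values = values, labels = labels, panel = panel,
                 batch_ids = as.character(batch_ids)),
            class = "batch_dataset")
}

#' @export
print.batch_dataset <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<batch_dataset> %d batches x %d metabolites x %d hours\n",
              d[1L], d[2L], d[3L]))
  cat("  labels:", paste(sprintf("%s=%d", names(table(x$labels)),
                                 table(x$labels)), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.batch_dataset <- function(x) dim(x$values)

#' Number of batches in a dataset
#' @param dataset A [batch_dataset()].
#' @return Integer count.
#' @export
n_batches <- function(dataset) dim(dataset$values)[1L]

#' Extract one batch as a metabolite-by-hour matrix
#'
#' @param dataset A [batch_dataset()].
#' @param i Batch index or batch id.
#' @return Numeric `J x K` matrix.
#' @export
get_batch <- function(dataset, i) {
  if (is.character(i)) i <- match(i, dataset$batch_ids)
  if (is.na(i) || i < 1L || i > n_batches(dataset)) stop("batch not found")
  m <- dataset$values[i, , , drop = TRUE]
  dim(m) <- dim(dataset$values)[2:3]
  dimnames(m) <- dimnames(dataset$values)[2:3]
  m
}

#' Subset a dataset by batch
#'
#' @param dataset A [batch_dataset()].
#' @param idx Integer/logical indices or batch ids. Duplicated indices are
#'   allowed (used for bootstrap training multisets); duplicated batches get
#'   suffixed ids.
#' @return A [batch_dataset()].
#' @export
subset_batches <- function(dataset, idx) {
  if (is.character(idx)) idx <- match(idx, dataset$batch_ids)
  if (anyNA(idx)) stop("batch not found")
  if (is.logical(idx)) idx <- which(idx)
  ids <- dataset$batch_ids[idx]
  if (anyDuplicated(ids)) ids <- make.unique(ids, sep = ".rep")
  batch_dataset(dataset$values[idx, , , drop = FALSE],
                dataset$labels[idx], dataset$panel, ids)
}

#' Truncate a dataset (or batch matrix) to the first k hours
#'
#' Used to fit per-hour online models and to form partial trajectories.
#'
#' @param dataset A [batch_dataset()].
#' @param k Last hour to keep, `1 <= k <= K`.
#' @return A [batch_dataset()] with K = k.
#' @export
truncate_hours <- function(dataset, k) {
  K <- dim(dataset$values)[3L]
  if (k < 1L || k > K) stop("k out of range")
  batch_dataset(dataset$values[, , seq_len(k), drop = FALSE],
                dataset$labels, dataset$panel, dataset$batch_ids)
}

#' Concatenate two datasets batch-wise
#'
#' @param a,b [batch_dataset()] objects sharing panel and K.
#' @return A [batch_dataset()].
#' @export
combine_batches <- function(a, b) {
  if (!identical(a$panel, b$panel)) stop("panels differ")
  if (dim(a$values)[3L] != dim(b$values)[3L]) stop("time dims differ")
  ids <- c(a$batch_ids, b$batch_ids)
  if (anyDuplicated(ids)) ids <- make.unique(ids, sep = ".")
  vals <- array(NA_real_, c(length(ids), dim(a$values)[2L], dim(a$values)[3L]))
  vals[seq_len(n_batches(a)), , ] <- a$values
  vals[n_batches(a) + seq_len(n_batches(b)), , ] <- b$values
  batch_dataset(vals, c(a$labels, b$labels), a$panel, ids)
}

#' Per-(metabolite, hour) mean trajectory of a dataset
#'
#' @param dataset A [batch_dataset()]; typically the fresh training set.
#' @return Numeric `J x K` matrix of means over batches.
#' @export
mean_trajectory <- function(dataset) {
  apply(dataset$values, c(2L, 3L), mean)
}
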