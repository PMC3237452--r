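#' Write a dataset as long-format CSV
#'
#' One row per (batch, metabolite, hour):
#' `batch_id, label, metabolite, time_hr, concentration`.
#'
#' @param dataset A [batch_dataset()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_panel_csv <- function(dataset, path) {
  d <- dim(dataset$values)
  df <- data.frame(
    batch_id = rep(dataset$batch_ids, times = d[2L] * d[3L]),
    label = rep(dataset$labels, times = d[2L] * d[3L]),
    metabolite = rep(rep(dataset$panel, each = d[1L]), times = d[3L]),
    time_hr = rep(seq_len(d[3L]), each = d[1L] * d[2L]),
    concentration = as.vector(dataset$values))
  df <- df[order(df$batch_id, match(df$metabolite, dataset$panel),
                 df$time_hr), ]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a long-format panel CSV into a dataset
#'
#' Validates keys and names: duplicated `(batch_id, metabolite, time_hr)`
#' rows, metabolites outside the panel, and ragged batches are rejected
#' with the offending keys named. Missing cells become `NA` (repairable
#' with [replace_invalid()]).
#'
#' @param path CSV path with columns `batch_id, label, metabolite,
#'   time_hr, concentration`.
#' @param panel Allowed metabolite names, defining the metabolite order
#'   (default [default_panel()]).
#' @return A [batch_dataset()].
#' @export
read_panel_csv <- function(path, panel = default_panel()) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("batch_id", "label", "metabolite", "time_hr", "concentration")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("missing columns: ", paste(missing_cols, collapse = ", "))
  unknown <- setdiff(unique(df$metabolite), panel)
  if (length(unknown))
    stop("unknown metabolite name(s): ", paste(unknown, collapse = ", "))
  key <- paste(df$batch_id, df$metabolite, df$time_hr, sep = "|")
  if (anyDuplicated(key))
    stop("duplicated (batch, metabolite, hour) key(s): ",
         paste(utils::head(unique(key[duplicated(key)]), 5L),
               collapse = "; "))
  batch_ids <- unique(df$batch_id)
  hours <- sort(unique(df$time_hr))
  if (!identical(as.integer(hours), seq_along(hours)))
    stop("time_hr must be 1..K")
  labels <- vapply(batch_ids, function(b) {
    l <- unique(df$label[df$batch_id == b])
    if (length(l) != 1L) stop("batch ", b, " has inconsistent labels")
    l
  }, character(1L))
  mets <- unique(df$metabolite)
  per_batch <- table(df$batch_id)
  if (length(unique(per_batch)) != 1L)
    stop("ragged batches: row counts differ (",
         paste(utils::head(names(per_batch), 5L), collapse = ", "), ")")
  vals <- array(NA_real_, c(length(batch_ids), length(panel),
                            length(hours)))
  i <- match(df$batch_id, batch_ids)
  j <- match(df$metabolite, panel)
  k <- match(df$time_hr, hours)
  vals[cbind(i, j, k)] <- df$concentration
  used <- panel %in% mets
  if (!all(used)) {
    vals <- vals[, used, drop = FALSE]
    panel <- panel[used]
  }
  batch_dataset(vals, labels, panel, batch_ids)
}

#' Export an SPE trace or contribution table as tidy CSV
#'
#' @param x An `spe_trace` data.frame or a `contribution_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tidy_csv <- function(x, path) {
  if (inherits(x, "contribution_table")) {
    J <- nrow(x$squared); K <- ncol(x$squared)
    x <- data.frame(batch_id = x$batch_id,
                    metabolite = rep(rownames(x$squared), K),
                    hour = rep(seq_len(K), each = J),
                    squared_contribution = as.vector(x$squared),
                    normalized_error = as.vector(x$normalized))
  }
  utils::write.csv(as.data.frame(x), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Serialize a fitted model to a portable JSON file
#'
#' Versioned, text-based serialization of `mpca_model` and
#' `mplsda_model` objects; numeric content is stored at full double
#' precision.
#'
#' @param model An `mpca_model` or `mplsda_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  kind <- class(model)[1L]
  if (!kind %in% c("mpca_model", "mplsda_model"))
    stop("unsupported model class: ", kind)
  pack <- function(x) {
    if (is.matrix(x)) {
      list(.matrix = TRUE, dim = dim(x), dimnames = dimnames(x),
           data = as.vector(x))
    } else if (is.list(x) && !is.data.frame(x)) {
      lapply(x, pack)
    } else x
  }
  payload <- list(format = "perfuseSPM-model", version = 1L, kind = kind,
                  fields = lapply(unclass(model), pack))
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE,
                       na = "null", null = "null")
  invisible(path)
}

#' Read a serialized model
#'
#' @param path Path written by [write_model()].
#' @return The restored model object.
#' @export
read_model <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE,
                                 simplifyDataFrame = FALSE,
                                 simplifyMatrix = FALSE)
  if (!identical(payload$format, "perfuseSPM-model"))
    stop("not a perfuseSPM model file")
  unpack <- function(x) {
    if (is.list(x) && isTRUE(x$.matrix)) {
      m <- matrix(unlist(x$data), unlist(x$dim)[1L], unlist(x$dim)[2L])
      if (!is.null(x$dimnames))
        dimnames(m) <- lapply(x$dimnames, function(d)
          if (is.null(d) || !length(d)) NULL else unlist(d))
      m
    } else if (is.list(x)) {
      lapply(x, unpack)
    } else x
  }
  f <- lapply(payload$fields, unpack)
  # restore simple vectors flattened by JSON
  f$scaler <- structure(f$scaler, class = "scaler_params")
  for (nm in intersect(c("limits_offline", "y_mean"), names(f)))
    f[[nm]] <- unlist(f[[nm]])
  for (nm in intersect(c("explained_variance", "singular_values",
                         "spe_train_offline", "spe_ref_offline", "alpha",
                         "r2x", "r2y"),
                       names(f)))
    f[[nm]] <- as.numeric(unlist(f[[nm]]))
  for (nm in intersect(c("panel", "class_order"), names(f)))
    f[[nm]] <- as.character(unlist(f[[nm]]))
  if (!is.null(f$limits_offline))
    names(f$limits_offline) <- paste0("alpha_", f$alpha)
  if (!is.null(f$y_mean)) names(f$y_mean) <- f$class_order
  structure(f, class = payload$kind)
}

#' Study configuration
#'
#' Bundles the constants of the monitoring/classification workflow: panel,
#' horizon K, component counts, significance levels, the ischemia-index
#' log base and threshold, online modes, cross-validation runs and the
#' study seed.
#'
#' @param panel Metabolite names.
#' @param K Hours per perfusion.
#' @param R_mpca,R_mpls Component counts (defaults 3).
#' @param alpha Significance levels (default `c(0.05, 0.01)`).
#' @param index_log_base Log base of the ischemia index (default 10).
#' @param index_threshold Alarm threshold on the log index (default 1.35).
#' @param online_spe_mode `"instantaneous"` or `"cumulative"`.
#' @param online_mpls_strategy `"truncated"` or `"zero_fill"`.
#' @param cv_runs Resampling runs (default 100).
#' @param seed Study seed.
#' @return List of class `study_config`.
#' @export
study_config <- function(panel = default_panel(), K = 6L, R_mpca = 3L,
                         R_mpls = 3L, alpha = c(0.05, 0.01),
                         index_log_base = 10, index_threshold = 1.35,
                         online_spe_mode = "instantaneous",
                         online_mpls_strategy = "truncated",
                         cv_runs = 100L, seed = 1L) {
  if (index_threshold <= 0) stop("index_threshold must be > 0")
  if (any(alpha <= 0 | alpha >= 1)) stop("alpha must be in (0, 1)")
  structure(list(panel = panel, K = as.integer(K),
                 R_mpca = as.integer(R_mpca), R_mpls = as.integer(R_mpls),
                 alpha = alpha, index_log_base = index_log_base,
                 index_threshold = index_threshold,
                 online_spe_mode = online_spe_mode,
                 online_mpls_strategy = online_mpls_strategy,
                 cv_runs = as.integer(cv_runs), seed = as.integer(seed)),
            class = "study_config")
}
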