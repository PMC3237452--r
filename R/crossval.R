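#' Draw one case-resampling training/test split
#'
#' Samples 5 fresh and 5 warm-ischemic batches with replacement for the
#' training multiset, capping the multiplicity of any single batch at
#' `max_select` (default 2) so the same perfusion cannot dominate a model.
#' The test set is every batch never drawn into training. A
#' without-replacement mode is available.
#'
#' @param dataset A [batch_dataset()] with labels in `{fresh, wi}`.
#' @param n_per_class Training draws per class (default 5).
#' @param max_select Multiplicity cap per batch within one training set
#'   (default 2). Ignored when `replace = FALSE`.
#' @param replace Sample with replacement (default TRUE, the
#'   case-resampling scheme).
#' @return List of class `cv_split` with `train` (integer indices, with
#'   multiplicity), `test` (indices), `selection_counts` (named counts).
#' @export
resample_split <- function(dataset, n_per_class = 5L, max_select = 2L,
                           replace = TRUE) {
  labels <- dataset$labels
  idx_by_class <- split(seq_along(labels), factor(labels, c("fresh", "wi")))
  train <- integer(0)
  for (cls in c("fresh", "wi")) {
    pool <- idx_by_class[[cls]]
    if (!replace) {
      if (length(pool) < n_per_class)
        stop("not enough ", cls, " batches for a without-replacement draw")
      train <- c(train, sample(pool, n_per_class))
      next
    }
    if (length(pool) * max_select < n_per_class)
      stop("multiplicity cap makes a ", n_per_class, "-draw of class ",
           cls, " infeasible")
    counts <- integer(length(pool))
    draws <- integer(0)
    for (d in seq_len(n_per_class)) {
      avail <- which(counts < max_select)
      pick <- avail[sample.int(length(avail), 1L)]
      counts[pick] <- counts[pick] + 1L
      draws <- c(draws, pool[pick])
    }
    train <- c(train, draws)
  }
  test <- setdiff(seq_along(labels), unique(train))
  sel <- table(factor(dataset$batch_ids[train],
                      levels = dataset$batch_ids))
  structure(list(train = train, test = test,
                 selection_counts = sel),
            class = "cv_split")
}

#' Case-resampling cross-validation of the MPLS-DA classifier
#'
#' Repeats `runs` times: draw a 5 fresh + 5 WI training multiset
#' ([resample_split()]), fit the classifier on it, predict every left-out
#' batch, and accumulate confusion counts. In `"offline"` mode one
#' full-trajectory model classifies each test batch once; in `"online"`
#' mode per-hour models ([fit_hourly_mpls()]) classify each test batch at
#' every hour and counts are kept per hour. Runs whose fit fails are
#' recorded and skipped, not silently dropped. Deterministic given `seed`.
#'
#' @param dataset A [batch_dataset()] with both classes.
#' @param runs Number of resampling runs (default 100).
#' @param R PLS components (default 3).
#' @param mode `"offline"` or `"online"`.
#' @param seed Integer RNG seed.
#' @param n_per_class,max_select Passed to [resample_split()].
#' @return Object of class `cv_result`: list with `runs`, `mode`,
#'   `confusion` (per-hour matrix of counts wi_as_wi, wi_as_fresh,
#'   fresh_as_wi, fresh_as_fresh; a single `"offline"` row in offline
#'   mode), `pooled` (summed counts), `metrics` (per-hour data.frame with
#'   sensitivity/specificity/accuracy), `pooled_metrics`, `failed_runs`,
#'   `splits` (list of draws for replay).
#' @export
run_cv <- function(dataset, runs = 100L, R = 3L,
                   mode = c("offline", "online"), seed = 1L,
                   n_per_class = 5L, max_select = 2L) {
  mode <- match.arg(mode)
  set.seed(seed)
  K <- dim(dataset$values)[3L]
  hours <- if (mode == "offline") "offline" else paste0("h", seq_len(K))
  conf <- matrix(0L, length(hours), 4L,
                 dimnames = list(hours, c("wi_as_wi", "wi_as_fresh",
                                          "fresh_as_wi", "fresh_as_fresh")))
  failed <- integer(0)
  splits <- vector("list", runs)
  skipped_empty <- 0L
  for (run in seq_len(runs)) {
    sp <- resample_split(dataset, n_per_class, max_select)
    splits[[run]] <- sp
    if (length(sp$test) == 0L) {
      warning("run ", run, ": empty test set, skipped")
      skipped_empty <- skipped_empty + 1L
      next
    }
    train_set <- subset_batches(dataset, sp$train)
    res <- tryCatch({
      if (mode == "offline") {
        model <- fit_mpls(train_set, R = R)
        preds <- predict_dataset(model, subset_batches(dataset, sp$test))
        list(hour = rep("offline", nrow(preds)), label = preds$label,
             pred = preds$predicted_class)
      } else {
        models <- fit_hourly_mpls(train_set, R = R)
        hour <- label <- pred <- character(0)
        for (i in sp$test) {
          b <- get_batch(dataset, i)
          for (k in seq_len(K)) {
            q <- online_predict(models, b, k)
            hour <- c(hour, paste0("h", k))
            label <- c(label, dataset$labels[i])
            pred <- c(pred, q$predicted_class)
          }
        }
        list(hour = hour, label = label, pred = pred)
      }
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failed <- c(failed, run)
      next
    }
    for (i in seq_along(res$label)) {
      cell <- paste0(ifelse(res$label[i] == "wi", "wi_as_", "fresh_as_"),
                     ifelse(res$pred[i] == "wi", "wi", "fresh"))
      conf[res$hour[i], cell] <- conf[res$hour[i], cell] + 1L
    }
  }
  pooled <- colSums(conf)
  metr <- function(cc) {
    sens <- if ((cc["wi_as_wi"] + cc["wi_as_fresh"]) > 0)
      cc["wi_as_wi"] / (cc["wi_as_wi"] + cc["wi_as_fresh"]) else NA_real_
    spec <- if ((cc["fresh_as_fresh"] + cc["fresh_as_wi"]) > 0)
      cc["fresh_as_fresh"] / (cc["fresh_as_fresh"] + cc["fresh_as_wi"])
      else NA_real_
    acc <- if (sum(cc) > 0)
      (cc["wi_as_wi"] + cc["fresh_as_fresh"]) / sum(cc) else NA_real_
    c(sensitivity = unname(sens), specificity = unname(spec),
      accuracy = unname(acc))
  }
  metrics <- as.data.frame(t(apply(conf, 1L, metr)))
  metrics <- cbind(hour = rownames(conf), metrics, row.names = NULL)
  structure(list(runs = runs, mode = mode, R = R, seed = seed,
                 confusion = conf, pooled = pooled,
                 metrics = metrics,
                 pooled_metrics = metr(pooled),
                 failed_runs = failed, skipped_empty = skipped_empty,
                 splits = splits),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %s, %d runs (%d failed, %d empty-test)\n",
              x$mode, x$runs, length(x$failed_runs), x$skipped_empty))
  print(round(x$pooled_metrics, 4))
  invisible(x)
}

#' Summarize a cross-validation result as tidy tables
#'
#' @param result A `cv_result` from [run_cv()].
#' @return List with `confusion` (pooled 2x2 data.frame: rows classified
#'   class, columns actual class) and `by_hour` (per-hour
#'   sensitivity/specificity/accuracy data.frame).
#' @export
summarize_cv <- function(result) {
  cc <- result$pooled
  if (sum(cc) == 0) {
    warning("empty cross-validation result")
    return(list(confusion = data.frame(), by_hour = data.frame()))
  }
  confusion <- data.frame(
    classified_as = c("wi", "fresh"),
    wi_actual = c(cc[["wi_as_wi"]], cc[["wi_as_fresh"]]),
    fresh_actual = c(cc[["fresh_as_wi"]], cc[["fresh_as_fresh"]]))
  list(confusion = confusion, by_hour = result$metrics)
}

#' Sensitivity/specificity arithmetic from raw confusion counts
#'
#' Warm-ischemic is the positive class: sensitivity is the fraction of WI
#' tests classified WI; specificity the fraction of fresh tests classified
#' fresh.
#'
#' @param wi_as_wi,wi_as_fresh,fresh_as_wi,fresh_as_fresh Counts.
#' @return Named numeric: sensitivity, specificity, accuracy.
#' @export
confusion_metrics <- function(wi_as_wi, wi_as_fresh, fresh_as_wi,
                              fresh_as_fresh) {
  c(sensitivity = wi_as_wi / (wi_as_wi + wi_as_fresh),
    specificity = fresh_as_fresh / (fresh_as_fresh + fresh_as_wi),
    accuracy = (wi_as_wi + fresh_as_fresh) /
      (wi_as_wi + wi_as_fresh + fresh_as_wi + fresh_as_fresh))
}
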