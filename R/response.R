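# The response-prediction protocol: stratified 3-fold cross-validation with
# mRMR selection on the training split only, gradient-boosted trees with
# default hyperparameters, a balanced-accuracy sweep over the number of kept
# features, and occurrence/rank aggregation of the selected sets.

POSITIVE_LABEL <- "responder"

encode_labels <- function(labels) {
  u <- sort(unique(as.character(labels)))
  if (length(u) != 2) abort("labels must have exactly two levels")
  if (POSITIVE_LABEL %in% u) {
    as.integer(as.character(labels) == POSITIVE_LABEL)
  } else {
    as.integer(as.character(labels) == u[2])
  }
}

#' Stratified cross-validation folds
#'
#' @param labels Binary label vector.
#' @param k Number of folds, default 3 (train 2/3, test 1/3).
#' @param seed Integer seed for the shuffle.
#' @return Integer vector of fold assignments (1..k) per sample; every fold
#'   holds both labels or an error is raised.
#' @export
cv_folds <- function(labels, k = 3, seed = 1) {
  y <- encode_labels(labels)
  set.seed(seed)
  fold <- integer(length(y))
  for (g in unique(y)) {
    idx <- sample(which(y == g))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  tab <- table(fold, y)
  if (any(tab == 0)) {
    abort("degenerate fold: a test fold lacks one of the labels")
  }
  fold
}

impute_median <- function(train, test) {
  med <- vapply(as.data.frame(train), function(col) {
    m <- median(col, na.rm = TRUE)
    if (is.na(m)) 0 else m
  }, numeric(1))
  fill <- function(m) {
    for (j in seq_len(ncol(m))) m[is.na(m[, j]), j] <- med[j]
    m
  }
  list(train = fill(train), test = fill(test))
}

fit_gbt <- function(x, y, nrounds = 100) {
  xgboost::xgb.train(
    params = list(objective = "binary:logistic", nthread = 1),
    data = xgboost::xgb.DMatrix(x, label = y, nthread = 1),
    nrounds = nrounds, verbose = 0
  )
}

predict_gbt <- function(model, x) {
  stats::predict(model, xgboost::xgb.DMatrix(x, nthread = 1))
}

#' Balanced accuracy
#'
#' Mean of sensitivity and specificity, robust to class imbalance.
#'
#' @param truth 0/1 truth vector.
#' @param prob Predicted probability of the positive class.
#' @param threshold Classification threshold, default 0.5.
#' @return Balanced accuracy in `[0, 1]`.
#' @export
balanced_accuracy <- function(truth, prob, threshold = 0.5) {
  pred <- as.integer(prob > threshold)
  sens <- sum(pred == 1 & truth == 1) / sum(truth == 1)
  spec <- sum(pred == 0 & truth == 0) / sum(truth == 0)
  (sens + spec) / 2
}

as_feature_matrix <- function(features) {
  df <- as.data.frame(features)
  if ("sample_id" %in% names(df)) df$sample_id <- NULL
  if ("label" %in% names(df)) df$label <- NULL
  x <- as.matrix(df)
  storage.mode(x) <- "double"
  x
}

#' Sweep the number of selected features under cross-validation
#'
#' For each fold, medians of the training split impute missing values, mRMR
#' ranks the features on the training split only, and a gradient-boosted
#' trees classifier (library-default hyperparameters) is fitted on the top
#' `N` features for every `N` in `n_range` and scored by balanced accuracy on
#' the held-out test fold. `n_best` is the `N` with the best mean balanced
#' accuracy across folds (smallest `N` on ties).
#'
#' @param features Data frame of numeric features by sample (a `sample_id`
#'   or `label` column, if present, is dropped).
#' @param labels Binary label vector (`responder` is the positive class when
#'   present).
#' @param n_range Integer vector of feature-subset sizes; default
#'   `1:min(107, n_features)`.
#' @param k Number of folds, default 3.
#' @param seed Seed for the stratified fold shuffle.
#' @param nrounds Boosting rounds, default 100.
#' @return An object of class `hf_sweep`: `per_fold` (tibble n x fold x
#'   balanced accuracy), `summary` (per-N mean), `n_best`, `orders` (the full
#'   per-fold mRMR rankings), `folds`, `seed`.
#' @export
sweep_n_features <- function(features, labels, n_range = NULL, k = 3,
                             seed = 1, nrounds = 100) {
  x <- as_feature_matrix(features)
  y <- encode_labels(labels)
  n_range <- n_range %||% seq_len(min(107L, ncol(x)))
  if (max(n_range) > ncol(x)) abort("n_range exceeds the number of features")
  fold <- cv_folds(labels, k = k, seed = seed)
  n_max <- max(n_range)
  orders <- vector("list", k)
  rows <- vector("list", k)
  for (l in seq_len(k)) {
    tr <- fold != l
    imp <- impute_median(x[tr, , drop = FALSE], x[!tr, , drop = FALSE])
    orders[[l]] <- mrmr_select(imp$train, y[tr], n = n_max)
    ba <- vapply(n_range, function(n) {
      keep <- orders[[l]][seq_len(n)]
      model <- fit_gbt(imp$train[, keep, drop = FALSE], y[tr],
                       nrounds = nrounds)
      balanced_accuracy(y[!tr],
                        predict_gbt(model, imp$test[, keep, drop = FALSE]))
    }, numeric(1))
    rows[[l]] <- tibble(n = n_range, fold = l, balanced_accuracy = ba)
  }
  per_fold <- bind_rows(rows)
  summary <- per_fold |>
    group_by(.data$n) |>
    summarise(mean_balanced_accuracy = mean(.data$balanced_accuracy),
              .groups = "drop")
  n_best <- summary$n[which.max(summary$mean_balanced_accuracy)]
  structure(list(per_fold = per_fold, summary = summary,
                 n_best = n_best, orders = orders, folds = fold,
                 seed = seed, nrounds = nrounds),
            class = "hf_sweep")
}

#' @export
print.hf_sweep <- function(x, ...) {
  best <- x$summary$mean_balanced_accuracy[x$summary$n == x$n_best]
  cat(sprintf(
    "<hf_sweep> %d folds, N in [%d, %d]; n_best = %d (mean balanced accuracy %.3f)\n",
    length(x$orders), min(x$summary$n), max(x$summary$n), x$n_best, best))
  invisible(x)
}

#' @export
tidy.hf_sweep <- function(x, ...) x$summary

#' @export
glance.hf_sweep <- function(x, ...) {
  tibble(n_best = x$n_best,
         best_mean_balanced_accuracy =
           max(x$summary$mean_balanced_accuracy),
         n_folds = length(x$orders))
}

#' Aggregate per-fold feature selections into occurrence counts and scores
#'
#' Each feature's occurrence count `c` is the number of cross-validation
#' splits whose selected set contains it. Its score `s` rewards early ranks:
#' a feature ranked `r` in a split contributes a pre-score `10^(n_best - r)`
#' (rank 1-based), the pre-scores are summed over splits, and `s` is the
#' log10 of the sum - so features are decade-separated by rank and ties in
#' `c` resolve in favour of better-ranked features.
#'
#' @param selections List of character vectors: the ordered selected set of
#'   each split (rank 1 first). Longer vectors are truncated to `n_best`.
#' @param n_best Number of features kept per split.
#' @return A tibble `feature`, `c`, `s`, sorted by (`c`, `s`) descending.
#' @export
aggregate_scores <- function(selections, n_best) {
  selections <- lapply(selections, function(s) {
    if (length(s) < n_best) abort("a split selected fewer than n_best features")
    s[seq_len(n_best)]
  })
  if (any(vapply(selections, anyDuplicated, integer(1)) > 0)) {
    abort("duplicate feature within one split's selection")
  }
  per_split <- bind_rows(lapply(seq_along(selections), function(l) {
    tibble(feature = selections[[l]], rank = seq_len(n_best), split = l)
  }))
  per_split |>
    group_by(.data$feature) |>
    summarise(c = n(),
              s = log10(sum(10^(n_best - .data$rank))),
              .groups = "drop") |>
    arrange(desc(.data$c), desc(.data$s))
}

# Step-interpolated true-positive rate of one fold's ROC on a common
# false-positive-rate grid (vertical averaging).
tpr_on_grid <- function(fpr, tpr, grid) {
  ord <- order(fpr, tpr)
  fpr <- fpr[ord]; tpr <- tpr[ord]
  vapply(grid, function(g) max(c(0, tpr[fpr <= g])), numeric(1))
}

#' Fit and evaluate the response classifier at a fixed number of features
#'
#' Runs the same stratified cross-validation as [sweep_n_features()] at a
#' single subset size: per fold, train-median imputation, mRMR selection of
#' `n_best` features on the training split, a gradient-boosted trees fit, and
#' an ROC curve from the held-out test-fold scores. The mean ROC curve is
#' obtained by vertical averaging over a common false-positive-rate grid.
#'
#' @inheritParams sweep_n_features
#' @param n_best Number of features per fold.
#' @param fpr_grid False-positive-rate grid for the mean curve.
#' @return An object of class `hf_response_fit`: `fold_metrics` (per-fold
#'   AUROC and balanced accuracy), `roc_points`, `mean_roc`, `mean_auc`,
#'   `sd_auc`, `selections`.
#' @export
fit_and_evaluate <- function(features, labels, n_best, k = 3, seed = 1,
                             nrounds = 100, fpr_grid = seq(0, 1, 0.01)) {
  x <- as_feature_matrix(features)
  y <- encode_labels(labels)
  fold <- cv_folds(labels, k = k, seed = seed)
  selections <- vector("list", k)
  fold_rows <- vector("list", k)
  roc_rows <- vector("list", k)
  grid_tpr <- matrix(NA_real_, k, length(fpr_grid))
  for (l in seq_len(k)) {
    tr <- fold != l
    imp <- impute_median(x[tr, , drop = FALSE], x[!tr, , drop = FALSE])
    sel <- mrmr_select(imp$train, y[tr], n = n_best)
    selections[[l]] <- sel
    model <- fit_gbt(imp$train[, sel, drop = FALSE], y[tr], nrounds = nrounds)
    prob <- predict_gbt(model, imp$test[, sel, drop = FALSE])
    roc <- pROC::roc(response = y[!tr], predictor = prob, quiet = TRUE,
                     direction = "<", levels = c(0, 1))
    fpr <- 1 - roc$specificities
    tpr <- roc$sensitivities
    roc_rows[[l]] <- tibble(fold = l, fpr = fpr, tpr = tpr)
    grid_tpr[l, ] <- tpr_on_grid(fpr, tpr, fpr_grid)
    fold_rows[[l]] <- tibble(fold = l, auc = as.numeric(pROC::auc(roc)),
                             balanced_accuracy = balanced_accuracy(y[!tr], prob))
  }
  fold_metrics <- bind_rows(fold_rows)
  structure(list(
    fold_metrics = fold_metrics,
    roc_points = bind_rows(roc_rows),
    mean_roc = tibble(fpr = fpr_grid, tpr = colMeans(grid_tpr)),
    mean_auc = mean(fold_metrics$auc),
    sd_auc = sd(fold_metrics$auc),
    selections = selections,
    n_best = n_best, seed = seed
  ), class = "hf_response_fit")
}

#' @export
print.hf_response_fit <- function(x, ...) {
  cat(sprintf("<hf_response_fit> %d folds, %d features/fold: mean AUROC %.3f +/- %.3f\n",
              nrow(x$fold_metrics), x$n_best, x$mean_auc, x$sd_auc))
  invisible(x)
}

#' @export
tidy.hf_response_fit <- function(x, ...) x$fold_metrics

#' @export
glance.hf_response_fit <- function(x, ...) {
  tibble(mean_auc = x$mean_auc, sd_auc = x$sd_auc,
         mean_balanced_accuracy = mean(x$fold_metrics$balanced_accuracy),
         n_best = x$n_best, n_folds = nrow(x$fold_metrics))
}

#' Run the full selection-and-scoring protocol
#'
#' Convenience driver chaining [sweep_n_features()] (to find `n_best`),
#' [aggregate_scores()] (occurrence counts and rank scores over the per-fold
#' selections truncated at `n_best`) and [fit_and_evaluate()] (ROC at
#' `n_best`), all on the same stratified folds.
#'
#' @inheritParams sweep_n_features
#' @param n_best Operating point for scoring and the final fit. `NULL`
#'   (default) uses the sweep's best `N`; a fixed value (e.g. 19, a typical
#'   published operating point for cohorts of this size) decouples the
#'   scoring from the fold-level noise of the sweep's argmax.
#' @return A list of class `hf_protocol` with elements `sweep`, `scores`,
#'   `fit`.
#' @export
response_protocol <- function(features, labels, n_range = NULL, k = 3,
                              seed = 1, nrounds = 100, n_best = NULL) {
  sweep <- sweep_n_features(features, labels, n_range = n_range, k = k,
                            seed = seed, nrounds = nrounds)
  n_best <- n_best %||% sweep$n_best
  scores <- aggregate_scores(sweep$orders, n_best)
  fit <- fit_and_evaluate(features, labels, n_best = n_best, k = k,
                          seed = seed, nrounds = nrounds)
  structure(list(sweep = sweep, scores = scores, fit = fit,
                 n_best = n_best),
            class = "hf_protocol")
}

#' @export
print.hf_protocol <- function(x, ...) {
  print(x$sweep); print(x$fit)
  cat("top features by (c, s):\n")
  print(head(x$scores, 8))
  invisible(x)
}
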