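# Minimum redundancy - maximum relevance feature selection, FCQ style:
# relevance is the one-way ANOVA F statistic of a feature against the binary
# label, redundancy the mean absolute Pearson correlation with the features
# already selected, and the greedy criterion their quotient.

# Vectorized two-group F statistic per column. Constant features get 0;
# a feature that separates the groups exactly gets Inf (within-group
# variance 0) and therefore wins the relevance ranking.
f_statistic <- function(x, y) {
  y <- as.integer(factor(y))
  n <- length(y)
  n1 <- sum(y == 1); n2 <- sum(y == 2)
  m1 <- colMeans(x[y == 1, , drop = FALSE])
  m2 <- colMeans(x[y == 2, , drop = FALSE])
  m <- colMeans(x)
  ssb <- n1 * (m1 - m)^2 + n2 * (m2 - m)^2
  ssw <- colSums((t(t(x[y == 1, , drop = FALSE]) - m1))^2) +
    colSums((t(t(x[y == 2, , drop = FALSE]) - m2))^2)
  f <- (ssb / 1) / (ssw / (n - 2))
  f[ssb == 0] <- 0  # constant or group-mean-equal features carry no signal
  f
}

#' mRMR greedy feature selection
#'
#' Forward selection of `n` features from a numeric table against a binary
#' label. The first pick maximizes relevance (the two-group F statistic);
#' each later pick maximizes the quotient of relevance over redundancy, where
#' redundancy is the mean absolute Pearson correlation with the already
#' selected features (floored at `red_floor` so that near-orthogonal
#' candidates cannot gain unbounded leverage). Ties resolve to the earlier
#' column, so the result is deterministic given the table.
#'
#' @param features Data frame or matrix of numeric features (columns) by
#'   samples (rows); missing values must be imputed beforehand (the
#'   cross-validation drivers impute with training-fold medians).
#' @param labels Binary label vector (two distinct values).
#' @param n Number of features to select, `1 <= n <= ncol(features)`.
#' @param red_floor Lower bound applied to mean redundancy, default 0.001.
#' @return Character vector of selected feature names, in selection order
#'   (rank 1 first).
#' @export
mrmr_select <- function(features, labels, n, red_floor = 1e-3) {
  x <- as.matrix(features)
  storage.mode(x) <- "double"
  if (anyNA(x)) abort("features contain missing values; impute first")
  if (length(unique(labels)) != 2) abort("labels must be binary")
  if (n < 1 || n > ncol(x)) abort("n must be in [1, n_features]")
  rel <- f_statistic(x, labels)
  p <- ncol(x)
  selected <- integer(0)
  red_sum <- numeric(p)  # running sum of |cor| with selected features
  remaining <- rep(TRUE, p)
  for (step in seq_len(n)) {
    if (step == 1) {
      score <- rel
    } else {
      red <- pmax(red_sum / length(selected), red_floor)
      score <- rel / red
    }
    score[!remaining] <- -Inf
    pick <- which.max(score)
    selected <- c(selected, pick)
    remaining[pick] <- FALSE
    if (step < n) {
      r <- suppressWarnings(as.vector(cor(x, x[, pick])))
      r[is.na(r)] <- 0  # constant columns: no usable correlation
      red_sum <- red_sum + abs(r)
    }
  }
  colnames(x)[selected]
}
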