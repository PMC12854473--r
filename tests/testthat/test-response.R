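test_that("mRMR picks maximal relevance first and penalizes redundancy", {
  set.seed(8)
  n <- 40
  y <- rep(c("responder", "non_responder"), each = n / 2)
  ind <- as.numeric(y == "responder")
  tab <- tibble::tibble(
    noise1 = rnorm(n),
    strong = ind + rnorm(n, sd = 0.6),  # strongest single feature
    copy = 0,                           # overwritten: exact duplicate
    weaker = ind + rnorm(n, sd = 1.0),  # informative, independent noise
    noise2 = rnorm(n),
    constant = rep(1, n)
  )
  tab$copy <- tab$strong
  sel <- mrmr_select(tab, y, 3)
  expect_equal(sel[1], "strong")
  # the exact duplicate is fully redundant; the weaker feature follows
  expect_equal(sel[2], "weaker")
  expect_false("copy" %in% sel[1:2])
  # constant feature carries zero relevance but raises no error
  expect_equal(unname(histofeatr:::f_statistic(as.matrix(tab), y)["constant"]), 0)
  expect_error(mrmr_select(tab, y, 99), "n_features")
  expect_error(mrmr_select(tibble::tibble(a = c(1, NA, 3, 4)),
                           y[1:4], 1), "missing")
})

test_that("mRMR selection order equals an independent greedy re-computation", {
  set.seed(31)
  n <- 30
  y <- rep(c(0, 1), each = n / 2)
  x <- matrix(rnorm(n * 6), n, 6,
              dimnames = list(NULL, paste0("f", 1:6)))
  x[, 1] <- x[, 1] + y * 1.5
  x[, 2] <- x[, 1] + rnorm(n, sd = 0.3)
  x[, 3] <- x[, 3] + y * 0.8
  got <- mrmr_select(x, y, 6)
  # oracle: re-evaluate the greedy FCQ criterion from scratch with stats::aov
  f_oracle <- vapply(seq_len(6), function(j) {
    summary(stats::aov(x[, j] ~ factor(y)))[[1]][["F value"]][1]
  }, numeric(1))
  sel <- character(0)
  remaining <- colnames(x)
  for (step in 1:6) {
    score <- vapply(remaining, function(f) {
      j <- match(f, colnames(x))
      if (length(sel) == 0) return(f_oracle[j])
      red <- mean(abs(vapply(sel, function(s) {
        stats::cor(x[, j], x[, match(s, colnames(x))])
      }, numeric(1))))
      f_oracle[j] / max(red, 1e-3)
    }, numeric(1))
    pick <- remaining[which.max(score)]
    sel <- c(sel, pick)
    remaining <- setdiff(remaining, pick)
  }
  expect_equal(got, sel)
})

test_that("cross-validation folds are stratified partitions", {
  y <- c(rep("responder", 28), rep("non_responder", 17))
  fold <- cv_folds(y, k = 3, seed = 4)
  expect_equal(sort(unique(fold)), 1:3)
  expect_equal(length(fold), 45)
  tab <- table(fold, y)
  expect_true(all(tab > 0))
  # roughly 2/3 train / 1/3 test per fold
  expect_true(all(abs(rowSums(tab) - 15) <= 1))
  expect_error(cv_folds(rep("responder", 9), k = 3), "two levels")
})

test_that("occurrence/rank aggregation follows the pre-score construction", {
  feats <- paste0("f", 1:40)
  set.seed(2)
  # one feature ranked first in all three splits of 19
  sel <- lapply(1:3, function(l) c("star", sample(feats, 18)))
  agg <- aggregate_scores(sel, n_best = 19)
  star <- agg[agg$feature == "star", ]
  expect_equal(star$c, 3L)
  expect_equal(star$s, log10(3 * 10^18))
  expect_equal(round(star$s, 3), 18.477)
  expect_equal(agg$feature[1], "star")
  # total occurrences always L * N_best
  expect_equal(sum(agg$c), 3 * 19)
  # a feature appearing once at the last rank scores exactly 0
  sel2 <- list(c(paste0("f", 1:18), "last"), paste0("g", 1:19),
               paste0("h", 1:19))
  agg2 <- aggregate_scores(sel2, n_best = 19)
  expect_equal(agg2$s[agg2$feature == "last"], 0)
  expect_equal(agg2$c[agg2$feature == "last"], 1L)
  expect_false("absent" %in% agg2$feature)
  # invariant to split ordering
  agg_rev <- aggregate_scores(rev(sel), n_best = 19)
  expect_equal(agg |> dplyr::arrange(feature),
               agg_rev |> dplyr::arrange(feature))
  expect_error(aggregate_scores(list(c("a", "a", "b")), n_best = 3),
               "duplicate")
})

test_that("balanced accuracy averages sensitivity and specificity", {
  truth <- c(1, 1, 1, 0, 0)
  expect_equal(balanced_accuracy(truth, c(0.9, 0.8, 0.2, 0.1, 0.6)),
               (2 / 3 + 1 / 2) / 2)
  expect_equal(balanced_accuracy(truth, truth), 1)
})

test_that("a perfectly informative feature saturates the sweep at N = 1", {
  set.seed(12)
  n <- 30
  y <- rep(c("responder", "non_responder"), each = n / 2)
  tab <- tibble::tibble(
    oracle = as.numeric(y == "responder"),  # the label indicator itself
    junk1 = rnorm(n), junk2 = rnorm(n), junk3 = rnorm(n)
  )
  sw <- sweep_n_features(tab, y, n_range = 1:4, seed = 3)
  expect_equal(sw$summary$mean_balanced_accuracy,
               rep(1, 4), tolerance = 1e-9)
  expect_equal(sw$n_best, 1L)
  expect_equal(unique(vapply(sw$orders, `[`, "", 1)), "oracle")

  fit <- fit_and_evaluate(tab, y, n_best = 1, seed = 3)
  expect_equal(fit$fold_metrics$auc, rep(1, 3))
  expect_equal(fit$mean_auc, 1)
  expect_equal(glance(fit)$mean_auc, 1)
  expect_equal(nrow(tidy(sw)), 4)
})

test_that("imputation statistics come from the training fold only", {
  x_tr <- matrix(c(1, 2, NA, 4, 10, 10, 10, 10), 4, 2)
  x_te <- matrix(c(NA, 7, NA, 1), 2, 2)
  imp <- histofeatr:::impute_median(x_tr, x_te)
  expect_equal(imp$train[3, 1], 2)   # median of 1, 2, 4
  expect_equal(imp$test[1, 1], 2)    # test filled with the train median
  expect_equal(imp$test[1, 2], 10)
  expect_false(anyNA(imp$train) || anyNA(imp$test))
})
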