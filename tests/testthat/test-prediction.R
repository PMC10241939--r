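# Classifier benchmarking: confusion-matrix metrics, AUC, stratified CV,
# importance ranking and the incremental-AUC curve.

test_that("metrics match direct substitution and handle zero denominators", {
  m <- compute_metrics(confusion_matrix(
    labels = c(1, 1, 1, 0, 0, 0, 0, 0, 0, 0),
    predicted = c(1, 1, 0, 1, 0, 0, 0, 0, 0, 0)))
  expect_equal(m[["accuracy"]], 0.8)
  expect_equal(m[["precision"]], 2 / 3)
  expect_equal(m[["sensitivity"]], 2 / 3)
  expect_equal(m[["specificity"]], 6 / 7)
  expect_equal(m[["f1"]], 2 / 3)
  perfect <- compute_metrics(c(tp = 5, fp = 0, fn = 0, tn = 5))
  expect_true(all(perfect == 1))
  degenerate <- compute_metrics(c(tp = 0, fp = 0, fn = 5, tn = 5))
  expect_true(is.na(degenerate[["precision"]]))
  expect_equal(degenerate[["sensitivity"]], 0)
  expect_error(compute_metrics(c(tp = 0, fp = 0, fn = 0, tn = 0)), "empty")
})

test_that("metrics agree with brute-force recounts on random instances", {
  set.seed(13)
  for (rep in 1:200) {
    n <- sample(5:60, 1)
    y <- rbinom(n, 1, 0.4)
    p <- rbinom(n, 1, 0.5)
    m <- compute_metrics(confusion_matrix(y, p))
    acc <- mean(y == p)
    expect_equal(m[["accuracy"]], acc)
    if (any(p == 1)) expect_equal(m[["precision"]],
                                  sum(y == 1 & p == 1) / sum(p == 1))
    if (any(y == 1)) expect_equal(m[["sensitivity"]],
                                  sum(y == 1 & p == 1) / sum(y == 1))
    if (any(y == 0)) expect_equal(m[["specificity"]],
                                  sum(y == 0 & p == 0) / sum(y == 0))
  }
})

test_that("rank-based AUC matches an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(17)
  for (rep in 1:25) {
    n <- sample(20:100, 1)
    y <- c(rep(1, 8), rbinom(n - 8, 1, 0.3))
    s <- round(rnorm(n), 1)   # coarse scores force ties
    ref <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                          direction = "<")))
    expect_equal(auc_score(y, s), ref, tolerance = 1e-12)
  }
  expect_equal(auc_score(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9)), 1)
  expect_true(is.na(auc_score(c(0, 0), c(0.1, 0.2))))
})

test_that("folds are stratified and seed-stable", {
  y <- rep(c(0, 1), c(180, 20))
  f <- metsflow:::make_folds(y, 10, seed = 3)
  expect_identical(f, metsflow:::make_folds(y, 10, seed = 3))
  for (i in 1:10) {
    expect_equal(sum(y == 1 & f == i), 2)
    expect_equal(sum(y == 0 & f == i), 18)
  }
})

test_that("cross-validation separates separable data and is deterministic", {
  fm <- separable_features()
  r1 <- run_cv(fm, "xgboost", k = 5, seed = 2)
  expect_gt(cv_auc(r1)[["mean"]], 0.99)
  r2 <- run_cv(fm, "xgboost", k = 5, seed = 2)
  expect_identical(r1$per_fold, r2$per_fold)
  expect_output(print(r1), "5-fold CV")
  expect_error(run_cv(fm[1:8, ], "xgboost", k = 5), "at least k")
})

test_that("all four classifiers run and rank separable data correctly", {
  fm <- separable_features(n = 200)
  for (clf in c("xgboost", "random_forest", "logistic_regression",
                "stacking")) {
    r <- run_cv(fm, clf, k = 3, seed = 4,
                params = list(nrounds = 30, ntree = 60))
    expect_gt(cv_auc(r)[["mean"]], 0.95)
  }
})

test_that("importance ranking is normalized, ordered and provenance-aware", {
  set.seed(5)
  n <- 300
  y <- rbinom(n, 1, 0.5)
  fm <- data.frame(good = y + rnorm(n, sd = 0.4),
                   noise1 = rnorm(n), noise2 = rnorm(n), ms_result = y)
  attr(fm, "provenance") <- c(good = "DFF", noise1 = "original_y4",
                              noise2 = "original_y4")
  rk <- feature_importance(fm, seed = 1, params = list(nrounds = 40))
  expect_equal(rk$feature[1], "good")
  expect_equal(sum(rk$score), 1, tolerance = 1e-9)
  expect_true(all(diff(rk$score) <= 0))
  expect_equal(importance_share(rk, 1, "DFF"), rk$score[1])
})

test_that("importance share sums group scores within the top of the ranking", {
  rk <- data.frame(feature = c("a", "b", "c"), score = c(0.5, 0.3, 0.2))
  class(rk) <- c("importance_ranking", "data.frame")
  prov <- c(a = "DFF", b = "DFF", c = "original_y4")
  expect_equal(importance_share(rk, 3, "DFF", prov), 0.8)
  expect_equal(importance_share(rk, 3, "original_latest", prov), 0.2)
  expect_equal(importance_share(rk, 2, "original_y4", prov), 0)
  expect_equal(importance_share(rk, 3, c("DFF", "original_y4"), prov), 1.0)
  expect_error(importance_share(rk, 4, "DFF", prov), "top_n")
  expect_error(importance_share(rk, 2, "bogus", prov), "unknown")
})

test_that("the incremental curve jumps at the informative feature then flattens", {
  set.seed(9)
  n <- 400
  y <- rep(0:1, each = n / 2)
  fm <- data.frame(signal = y * 2 + rnorm(n, sd = 0.5),
                   n1 = rnorm(n), n2 = rnorm(n), n3 = rnorm(n),
                   n4 = rnorm(n), ms_result = y)
  rk <- feature_importance(fm, seed = 2, params = list(nrounds = 30))
  cur <- incremental_auc_curve(fm, rk, k = 4, seed = 2,
                               params = list(nrounds = 30))
  expect_equal(nrow(cur$curve), 5)
  expect_gt(cur$curve$mean_auc[1], 0.95)          # signal ranked first
  expect_lte(cur$convergence_n, 5)
  expect_lt(max(abs(diff(cur$curve$mean_auc[-1]))), 0.05)  # flat tail
  expect_error(incremental_auc_curve(fm, rk[0, ], k = 4), "empty")
})
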