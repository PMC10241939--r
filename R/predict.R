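#' Confusion matrix from labels and hard predictions
#'
#' @param labels 0/1 truth vector.
#' @param predicted 0/1 prediction vector.
#' @return Named integer vector `tp, fp, fn, tn` of class
#'   `confusion_matrix`.
#' @export
confusion_matrix <- function(labels, predicted) {
  stopifnot(length(labels) == length(predicted))
  out <- c(tp = sum(labels == 1 & predicted == 1),
           fp = sum(labels == 0 & predicted == 1),
           fn = sum(labels == 1 & predicted == 0),
           tn = sum(labels == 0 & predicted == 0))
  structure(as.integer(out), names = names(out),
            class = "confusion_matrix")
}

#' Classification metrics from a confusion matrix
#'
#' Accuracy `(TP+TN)/n`, precision `TP/(TP+FP)`, sensitivity `TP/(TP+FN)`,
#' specificity `TN/(TN+FP)` and F1 `2 PR * SE / (PR + SE)`. A metric whose
#' denominator is zero is reported as `NA` rather than 0.
#'
#' @param cm A [confusion_matrix()] or named vector with `tp, fp, fn, tn`.
#' @return Named numeric vector of the five metrics.
#' @export
compute_metrics <- function(cm) {
  tp <- cm[["tp"]]; fp <- cm[["fp"]]; fn <- cm[["fn"]]; tn <- cm[["tn"]]
  n <- tp + fp + fn + tn
  if (n == 0) stop("empty confusion matrix")
  div <- function(num, den) if (den > 0) num / den else NA_real_
  precision <- div(tp, tp + fp)
  sensitivity <- div(tp, tp + fn)
  f1 <- if (!is.na(precision) && !is.na(sensitivity) &&
            precision + sensitivity > 0)
    2 * precision * sensitivity / (precision + sensitivity) else NA_real_
  c(accuracy = (tp + tn) / n,
    precision = precision,
    sensitivity = sensitivity,
    specificity = div(tn, tn + fp),
    f1 = f1)
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUC with midrank tie handling: the probability
#' that a random positive scores above a random negative, counting ties as
#' one half.
#'
#' @param labels 0/1 truth vector.
#' @param scores Numeric scores, higher = more positive.
#' @return AUC in \[0, 1\]; `NA` if either class is absent.
#' @export
auc_score <- function(labels, scores) {
  stopifnot(length(labels) == length(scores))
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Stratified fold assignment: each class spread evenly over k folds.
make_folds <- function(y, k, seed) {
  set.seed(seed)
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

.default_xgb_params <- function() {
  list(objective = "binary:logistic", eta = 0.1, max_depth = 4,
       min_child_weight = 5, subsample = 0.8, colsample_bytree = 0.8,
       nthread = 1, nrounds = 150)
}

# Booster fit through the version-stable xgb.train/xgb.DMatrix interface.
.fit_xgb <- function(x, y, seed, params = list()) {
  p <- utils::modifyList(.default_xgb_params(), params)
  p$ntree <- NULL  # random-forest knob that may ride along in shared params
  nrounds <- p$nrounds
  p$nrounds <- NULL
  p$seed <- seed
  dtrain <- xgboost::xgb.DMatrix(x, label = y, nthread = 1)
  xgboost::xgb.train(params = p, data = dtrain, nrounds = nrounds,
                     verbose = 0)
}

# Fit one classifier on a numeric matrix; returns function(newx) -> prob.
.fit_classifier <- function(x, y, classifier, seed, params = list()) {
  set.seed(seed)
  if (classifier == "xgboost") {
    fit <- .fit_xgb(x, y, seed, params)
    function(newx)
      stats::predict(fit, xgboost::xgb.DMatrix(newx, nthread = 1))
  } else if (classifier == "random_forest") {
    ntree <- if (!is.null(params$ntree)) params$ntree else 300
    fit <- randomForest::randomForest(x = x, y = factor(y, levels = 0:1),
                                      ntree = ntree)
    function(newx) stats::predict(fit, newx, type = "prob")[, "1"]
  } else if (classifier == "logistic_regression") {
    df <- data.frame(x)
    df$.y <- y
    fit <- suppressWarnings(stats::glm(.y ~ ., data = df,
                                       family = stats::binomial()))
    function(newx) {
      suppressWarnings(
        as.numeric(stats::predict(fit, data.frame(newx),
                                  type = "response")))
    }
  } else if (classifier == "stacking") {
    .fit_stacking(x, y, seed, params)
  } else {
    stop("unknown classifier: ", classifier)
  }
}

# Stacking: out-of-fold probabilities of the two base learners (XGBoost +
# random forest) feed a logistic meta-learner; the shipped combiner is the
# probability-averaging meta-model rather than a hard majority vote.
.fit_stacking <- function(x, y, seed, params = list(), inner_k = 5) {
  fold <- make_folds(y, inner_k, seed + 71)
  oof <- matrix(NA_real_, nrow(x), 2,
                dimnames = list(NULL, c("xgb", "rf")))
  for (i in seq_len(inner_k)) {
    tr <- fold != i
    p_xgb <- .fit_classifier(x[tr, , drop = FALSE], y[tr], "xgboost",
                             seed + i, params)
    p_rf <- .fit_classifier(x[tr, , drop = FALSE], y[tr], "random_forest",
                            seed + 100 + i, params)
    oof[!tr, "xgb"] <- p_xgb(x[!tr, , drop = FALSE])
    oof[!tr, "rf"] <- p_rf(x[!tr, , drop = FALSE])
  }
  meta_df <- data.frame(oof, .y = y)
  meta <- suppressWarnings(stats::glm(.y ~ xgb + rf, data = meta_df,
                                      family = stats::binomial()))
  base_xgb <- .fit_classifier(x, y, "xgboost", seed + 7, params)
  base_rf <- .fit_classifier(x, y, "random_forest", seed + 8, params)
  function(newx) {
    nd <- data.frame(xgb = base_xgb(newx), rf = base_rf(newx))
    suppressWarnings(as.numeric(stats::predict(meta, nd,
                                               type = "response")))
  }
}

#' Stratified k-fold cross-validation of a MetS classifier
#'
#' Folds are stratified on the label (with ~8.5% positives, unstratified
#' folds are unstable). Per fold, the model is fit on the training part and
#' scored on the held-out part; AUC, and threshold metrics at
#' `threshold`, are computed per fold from the out-of-fold probabilities,
#' then summarized as mean and SD across folds. Deterministic given `seed`.
#'
#' @param features Feature matrix from [build_feature_matrix()] (numeric
#'   columns plus `ms_result`), or any data.frame shaped that way.
#' @param classifier `"xgboost"` (default), `"random_forest"`,
#'   `"stacking"` or `"logistic_regression"`.
#' @param k Number of folds (default 10).
#' @param seed Integer seed.
#' @param threshold Probability cut for the confusion-matrix metrics
#'   (default 0.5).
#' @param params Named list of classifier hyperparameters overriding the
#'   documented defaults.
#' @param feature_set Optional label describing the feature set, carried
#'   into the report.
#' @return A `cv_report`: per-fold metric table, `summary` (mean, sd per
#'   metric), fold assignment, seed.
#' @export
run_cv <- function(features, classifier = c("xgboost", "random_forest",
                                            "stacking",
                                            "logistic_regression"),
                   k = 10, seed = 1, threshold = 0.5, params = list(),
                   feature_set = NULL) {
  classifier <- match.arg(classifier)
  y <- features$ms_result
  x <- as.matrix(features[setdiff(names(features), "ms_result")])
  if (!is.numeric(x)) stop("non-numeric feature column")
  if (anyNA(x) || any(!is.finite(x))) stop("non-finite feature values")
  if (sum(y == 1) < k || sum(y == 0) < k)
    stop("need at least k samples of each class")
  fold <- make_folds(y, k, seed)
  rows <- vector("list", k)
  for (i in seq_len(k)) {
    tr <- fold != i
    predict_prob <- .fit_classifier(x[tr, , drop = FALSE], y[tr],
                                    classifier, seed + i, params)
    p <- predict_prob(x[!tr, , drop = FALSE])
    cm <- confusion_matrix(y[!tr], as.integer(p >= threshold))
    rows[[i]] <- c(fold = i, auc = auc_score(y[!tr], p),
                   compute_metrics(cm))
  }
  per_fold <- as.data.frame(do.call(rbind, rows))
  mets <- setdiff(names(per_fold), "fold")
  summary <- data.frame(
    metric = mets,
    mean = vapply(mets, function(m) mean(per_fold[[m]], na.rm = TRUE),
                  numeric(1)),
    sd = vapply(mets, function(m) stats::sd(per_fold[[m]], na.rm = TRUE),
                numeric(1)),
    row.names = NULL)
  structure(list(classifier = classifier, feature_set = feature_set,
                 k = k, seed = seed, threshold = threshold,
                 per_fold = per_fold, summary = summary, folds = fold),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("%d-fold CV, classifier = %s%s\n", x$k, x$classifier,
              if (!is.null(x$feature_set))
                paste0(", features = ", x$feature_set) else ""))
  s <- x$summary
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-12s %.3f (+/- %.3f)\n", s$metric[i], s$mean[i],
                s$sd[i]))
  invisible(x)
}

#' Mean AUC of a cross-validation report
#'
#' @param report A `cv_report`.
#' @return Named vector `mean`, `sd` of the fold AUCs.
#' @export
cv_auc <- function(report) {
  s <- report$summary
  c(mean = s$mean[s$metric == "auc"], sd = s$sd[s$metric == "auc"])
}

#' XGBoost feature-importance ranking
#'
#' Gain-based importance from a single full-data fit, normalized to sum to
#' one over all candidate features; features the model never split on get
#' score zero. Ties (including the zeros) are broken lexicographically so
#' the ranking is deterministic.
#'
#' @inheritParams run_cv
#' @return Data.frame `feature, score` (descending), class
#'   `importance_ranking`, with the feature provenance map carried over in
#'   `attr(, "provenance")`.
#' @export
feature_importance <- function(features, seed = 1, params = list()) {
  y <- features$ms_result
  x <- as.matrix(features[setdiff(names(features), "ms_result")])
  set.seed(seed)
  fit <- .fit_xgb(x, y, seed, params)
  imp <- xgboost::xgb.importance(model = fit)
  score <- stats::setNames(rep(0, ncol(x)), colnames(x))
  score[imp$Feature] <- imp$Gain
  if (sum(score) > 0) score <- score / sum(score)
  out <- data.frame(feature = names(score), score = unname(score),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$score, out$feature), ]
  rownames(out) <- NULL
  class(out) <- c("importance_ranking", "data.frame")
  prov <- attr(features, "provenance")
  if (!is.null(prov)) attr(out, "provenance") <- prov
  out
}

#' Incremental-feature AUC curve
#'
#' Adds features one at a time in ranking order, running a full
#' cross-validation at each size, and reports where the curve converges:
#' the first size at which `consecutive` successive additions each gained
#' less than `tol` AUC.
#'
#' @param features Feature matrix with `ms_result`.
#' @param ranking An `importance_ranking` covering the candidate features.
#' @param classifier,k,seed,params As in [run_cv()].
#' @param tol Minimal per-feature AUC gain still counted as growth
#'   (default 0.002).
#' @param consecutive Number of successive below-`tol` gains that defines
#'   convergence (default 3).
#' @return List with `curve` (data.frame `n_features, mean_auc, sd_auc`)
#'   and `convergence_n`.
#' @export
incremental_auc_curve <- function(features, ranking,
                                  classifier = "xgboost", k = 10, seed = 1,
                                  params = list(), tol = 0.002,
                                  consecutive = 3) {
  if (!nrow(ranking)) stop("empty ranking")
  feats <- ranking$feature
  missing_cols <- setdiff(feats, names(features))
  if (length(missing_cols))
    stop("ranking names features absent from the matrix: ",
         paste(missing_cols, collapse = ", "))
  rows <- vector("list", length(feats))
  for (n in seq_along(feats)) {
    sub <- features[c(feats[seq_len(n)], "ms_result")]
    for (at in c("provenance", "scale_max"))
      attr(sub, at) <- attr(features, at)
    rep <- run_cv(sub, classifier = classifier, k = k, seed = seed,
                  params = params)
    a <- cv_auc(rep)
    rows[[n]] <- c(n_features = n, mean_auc = a[["mean"]],
                   sd_auc = a[["sd"]])
  }
  curve <- as.data.frame(do.call(rbind, rows))
  gains <- diff(curve$mean_auc)
  conv <- nrow(curve)
  if (length(gains) >= consecutive) {
    below <- gains < tol
    run <- stats::filter(below, rep(1, consecutive), sides = 1)
    hit <- which(run == consecutive)
    if (length(hit)) conv <- hit[1] + 1 - consecutive
  }
  list(curve = curve, convergence_n = conv)
}

#' Importance share of a feature-provenance group
#'
#' Fraction of the (normalized) importance held by features of the given
#' provenance group among the top `top_n` of the ranking — e.g. the share
#' of the DFF columns among the selected risk factors.
#'
#' @param ranking An `importance_ranking` with a provenance attribute, or a
#'   `feature, score` data.frame plus an explicit `provenance` map.
#' @param top_n How many top-ranked features to consider.
#' @param group Provenance tag(s): `"DFF"`, `"DNF"`, `"DSF"`,
#'   `"original_y1"`..`"original_y4"`, `"original_latest"` (alias for
#'   `original_y4`), `"demographic"`.
#' @param provenance Named map feature -> tag; default taken from the
#'   ranking attribute.
#' @return Numeric share in \[0, 1\].
#' @export
importance_share <- function(ranking, top_n, group,
                             provenance = attr(ranking, "provenance")) {
  if (is.null(provenance)) stop("no provenance map available")
  if (top_n > nrow(ranking)) stop("top_n exceeds ranking length")
  group <- sub("^original_latest$", "original_y4", group)
  known <- unique(c(provenance, "original_y4"))
  bad <- setdiff(group, known)
  if (length(bad)) stop("unknown provenance tag(s): ",
                        paste(bad, collapse = ", "))
  top <- ranking[seq_len(top_n), ]
  sum(top$score[provenance[top$feature] %in% group])
}
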