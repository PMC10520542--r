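#' Cross-validation configuration
#'
#' Outer loop for model assessment (leave-one-out by default, or stratified
#' k-fold for the costlier ensemble learners), inner stratified k-fold for
#' hyperparameter optimisation. One global seed fans out to per-outer-fold
#' seeds drawn once up front, so folds are reproducible and independent of
#' evaluation order.
#'
#' @param outer `"leave_one_out"` or `"stratified_kfold"`.
#' @param outer_k outer fold count when stratified (>= 2).
#' @param inner_folds inner stratified fold count (>= 2), default 4.
#' @param inner_metric `"accuracy"` (default; predicted class at 0.5) or
#'   `"auc"`.
#' @param mice_iterations chained-equations sweeps per fold.
#' @param seed global integer seed.
#' @return object of class `cv_config`.
#' @export
cv_config <- function(outer = c("leave_one_out", "stratified_kfold"),
                      outer_k = 4L, inner_folds = 4L,
                      inner_metric = c("accuracy", "auc"),
                      mice_iterations = 10L, seed = 1L) {
  outer <- match.arg(outer)
  inner_metric <- match.arg(inner_metric)
  stopifnot(inner_folds >= 2, outer_k >= 2, mice_iterations >= 1)
  structure(list(outer = outer, outer_k = as.integer(outer_k),
                 inner_folds = as.integer(inner_folds),
                 inner_metric = inner_metric,
                 mice_iterations = as.integer(mice_iterations),
                 seed = as.integer(seed)),
            class = "cv_config")
}

#' Stratified fold assignment
#'
#' Shuffles each class independently and deals it round-robin across `k`
#' folds, so every fold's class balance matches the whole as closely as the
#' integers allow.
#'
#' @param y binary outcome vector.
#' @param k number of folds.
#' @param seed integer seed.
#' @return integer vector of fold ids in 1..k.
#' @export
stratified_folds <- function(y, k, seed = 1) {
  if (min(table(y)) < k) {
    stop("cannot build ", k, " stratified folds: a class has fewer than ",
         k, " samples")
  }
  set.seed(seed)
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

# Mean inner-CV metric for each hyperparameter candidate.
.inner_grid_search <- function(x, y, model, cv, seed) {
  folds <- stratified_folds(y, cv$inner_folds, seed)
  grid <- model$hyper_grid
  scores <- matrix(NA_real_, cv$inner_folds, nrow(grid))
  for (f in seq_len(cv$inner_folds)) {
    tr <- folds != f
    w <- if (model$class_weighting) {
      .sample_weights(y[tr], class_weights(y[tr]))
    } else rep(1, sum(tr))
    xt <- x[tr, , drop = FALSE]; xv <- x[!tr, , drop = FALSE]
    if (model$family == "sparse_logistic") {
      coefs <- .fit_sparse_logistic_path(xt, y[tr], grid$C, w)
      probs <- apply(coefs, 2, .logistic_prob, x = xv)
      if (is.null(dim(probs))) probs <- matrix(probs, nrow = 1)
      scores[f, ] <- apply(probs, 2, .inner_metric_value,
                           y = y[!tr], metric = cv$inner_metric)
    } else {
      for (g in seq_len(nrow(grid))) {
        fit <- fit_learner(model$family, xt, y[tr], grid[g, , drop = FALSE], w)
        scores[f, g] <- .inner_metric_value(predict_prob(fit, xv), y[!tr],
                                            cv$inner_metric)
      }
    }
  }
  mean_scores <- colMeans(scores)
  # ties break toward the first candidate in declared grid order
  which.max(mean_scores)
}

.inner_metric_value <- function(prob, y, metric) {
  if (metric == "accuracy") {
    mean((prob >= 0.5) == (y == 1))
  } else {
    if (length(unique(y)) < 2) return(NA_real_)
    .auc_trapezoid(prob, y)
  }
}

# One fully leakage-safe outer step: impute and scale on training rows only,
# tune by inner CV, refit, predict the held-out rows.
.outer_step <- function(x_raw, y, test_idx, model, cv, seed) {
  tr_idx <- setdiff(seq_along(y), test_idx)
  imp <- mice_impute(x_raw[tr_idx, , drop = FALSE],
                     x_raw[test_idx, , drop = FALSE],
                     iterations = cv$mice_iterations)
  sc <- fit_scaler(imp$train)
  xt <- apply_scaler(sc, imp$train)
  xv <- apply_scaler(sc, imp$apply_to)
  best <- .inner_grid_search(xt, y[tr_idx], model, cv, seed)
  hyper <- model$hyper_grid[best, , drop = FALSE]
  w <- if (model$class_weighting) {
    .sample_weights(y[tr_idx], class_weights(y[tr_idx]))
  } else NULL
  set.seed(seed + 1L)  # resampling learners (bagging, forests)
  fit <- fit_learner(model$family, xt, y[tr_idx], hyper, w)
  list(prob = predict_prob(fit, xv), hyper = hyper,
       features = selected_features(fit))
}

#' Nested cross-validated evaluation
#'
#' The evaluation engine: an outer loop (leave-one-out or stratified k-fold)
#' holds samples out for assessment; inside every outer training fold,
#' imputation and standardisation are fitted from scratch, and an inner
#' stratified k-fold grid search picks the hyperparameters (ties to the
#' first grid entry). The model is refit on the full outer training fold and
#' its predictions on the held-out samples are pooled across folds — the
#' object every downstream metric (ROC, Brier, cut-point scan, DCA)
#' consumes. For the sparse logistic family the nonzero-coefficient set of
#' each outer fold is recorded for stability accounting.
#'
#' @param table a labelled [cohort_table()] (rows with NA outcome are
#'   dropped).
#' @param model a [model_spec()].
#' @param cv a [cv_config()].
#' @param features cohort columns to use as predictors.
#' @return object of class `aggregated_predictions`: data.frame with
#'   columns id, fold, prob, label; attributes `fold_hyper`,
#'   `fold_features`, `feature_names`.
#' @export
nested_cv_evaluate <- function(table, model, cv,
                               features = c("a_fg", "a_hba1c")) {
  y_all <- outcome_binary(table)
  keep <- !is.na(y_all)
  table <- table[keep, , drop = FALSE]
  y <- y_all[keep]
  if (min(table(y)) < 2) stop("need at least 2 samples in each class")
  x_raw <- build_feature_matrix(table, features)
  n <- length(y)

  if (cv$outer == "leave_one_out") {
    outer_sets <- as.list(seq_len(n))
  } else {
    ofold <- stratified_folds(y, cv$outer_k, cv$seed)
    outer_sets <- lapply(seq_len(cv$outer_k), function(f) which(ofold == f))
  }
  set.seed(cv$seed)
  fold_seeds <- sample.int(.Machine$integer.max - 1L, length(outer_sets))

  prob <- rep(NA_real_, n)
  fold_of <- rep(NA_integer_, n)
  hypers <- vector("list", length(outer_sets))
  feats <- vector("list", length(outer_sets))
  for (f in seq_along(outer_sets)) {
    step <- .outer_step(x_raw, y, outer_sets[[f]], model, cv, fold_seeds[f])
    prob[outer_sets[[f]]] <- step$prob
    fold_of[outer_sets[[f]]] <- f
    hypers[[f]] <- step$hyper
    feats[[f]] <- step$features
  }
  aggregated_predictions(data.frame(id = table$id, fold = fold_of,
                                    prob = prob, label = y,
                                    stringsAsFactors = FALSE),
                         fold_hyper = hypers, fold_features = feats,
                         feature_names = colnames(x_raw))
}

#' Construct an aggregated-predictions object
#'
#' @param df data.frame with columns id, fold, prob, label (one row per
#'   sample, probabilities finite in [0,1]).
#' @param fold_hyper,fold_features per-outer-fold chosen hyperparameters and
#'   selected-feature sets.
#' @param feature_names feature universe offered to the learner.
#' @return object of class `aggregated_predictions`.
#' @export
aggregated_predictions <- function(df, fold_hyper = NULL,
                                   fold_features = NULL,
                                   feature_names = NULL) {
  stopifnot(all(c("id", "fold", "prob", "label") %in% names(df)))
  if (anyDuplicated(df$id)) stop("exactly one prediction per sample required")
  if (any(!is.finite(df$prob))) stop("probabilities must be finite")
  structure(df, class = c("aggregated_predictions", "data.frame"),
            fold_hyper = fold_hyper, fold_features = fold_features,
            feature_names = feature_names)
}

# Trapezoidal AUC over the tie-grouped ROC; equals the Mann-Whitney
# concordance probability with ties counted 1/2.
.auc_trapezoid <- function(prob, y) {
  roc <- .roc_points(prob, y)
  sum(diff(roc$fpr) * (utils::head(roc$tpr, -1) + utils::tail(roc$tpr, -1)) / 2)
}

.roc_points <- function(prob, y) {
  P <- sum(y == 1); N <- sum(y == 0)
  thr <- sort(unique(prob), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(prob >= t & y == 1) / P, 0)
  fpr <- vapply(thr, function(t) sum(prob >= t & y == 0) / N, 0)
  data.frame(threshold = c(Inf, thr), tpr = c(0, tpr), fpr = c(0, fpr))
}

#' ROC curve and AUC of pooled predictions
#'
#' Thresholds at the distinct predicted probabilities (classify positive at
#' `prob >= threshold`); AUC by the trapezoid rule, which equals the
#' Mann-Whitney concordance probability with ties counted 1/2.
#'
#' @param preds an `aggregated_predictions` object (or data.frame with
#'   `prob`, `label`).
#' @return object of class `roc_curve`: list with `points` (threshold, tpr,
#'   fpr; tpr/fpr non-decreasing as the threshold decreases) and `auc`.
#' @export
roc_auc <- function(preds) {
  if (length(unique(preds$label)) < 2) {
    stop("ROC requires both classes to be present")
  }
  pts <- .roc_points(preds$prob, preds$label)
  structure(list(points = pts,
                 auc = sum(diff(pts$fpr) *
                             (utils::head(pts$tpr, -1) + utils::tail(pts$tpr, -1)) / 2)),
            class = "roc_curve")
}

#' Brier score of pooled predictions
#'
#' Mean squared difference between the predicted probability and the 0/1
#' label; lower is better calibrated.
#'
#' @param preds an `aggregated_predictions` object.
#' @return numeric scalar.
#' @export
brier <- function(preds) {
  mean((preds$prob - preds$label)^2)
}

#' Feature-selection stability across outer folds
#'
#' For each feature offered to the sparse logistic learner, the number (and
#' fraction) of outer folds in which its coefficient was nonzero.
#'
#' @param preds an `aggregated_predictions` object carrying fold-level
#'   selected-feature sets.
#' @return data.frame with columns feature, count, fraction.
#' @export
feature_stability <- function(preds) {
  feats <- attr(preds, "fold_features")
  universe <- attr(preds, "feature_names")
  if (is.null(feats) || is.null(universe)) {
    stop("predictions carry no fold-level selected-feature sets")
  }
  counts <- vapply(universe, function(f) {
    sum(vapply(feats, function(s) f %in% s, logical(1)))
  }, integer(1))
  data.frame(feature = universe, count = counts,
             fraction = counts / length(feats), row.names = NULL,
             stringsAsFactors = FALSE)
}
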