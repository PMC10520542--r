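# Learner layer. The bespoke contract in this package is the balancing,
# nesting, pooling and stability accounting; the optimisers behind the
# individual learners are standard implementations (glmnet coordinate
# descent, rpart, randomForest, xgboost).

#' Model specification
#'
#' @param family one of `sparse_logistic`, `decision_tree`, `bagged_trees`,
#'   `random_forest`, `gradient_boosted_trees`.
#' @param hyper_grid data.frame of candidate hyperparameter combinations
#'   (one row per candidate, columns named per family); default
#'   [default_hyper_grid()].
#' @param class_weighting apply balanced class weights (default TRUE).
#' @return object of class `model_spec`.
#' @export
model_spec <- function(family = c("sparse_logistic", "decision_tree",
                                  "bagged_trees", "random_forest",
                                  "gradient_boosted_trees"),
                       hyper_grid = NULL, class_weighting = TRUE) {
  family <- match.arg(family)
  if (is.null(hyper_grid)) hyper_grid <- default_hyper_grid(family)
  if (nrow(hyper_grid) == 0) stop("hyper_grid must be non-empty")
  structure(list(family = family, hyper_grid = hyper_grid,
                 class_weighting = isTRUE(class_weighting)),
            class = "model_spec")
}

#' Default hyperparameter grids
#'
#' For `sparse_logistic` the tunable is the inverse regularisation strength
#' C (10 points, log-spaced 1e-3 to 1e3). Tree families get small grids over
#' their structural controls.
#'
#' @param family learner family, see [model_spec()].
#' @return data.frame, one row per candidate, in declared search order.
#' @export
default_hyper_grid <- function(family) {
  switch(family,
    sparse_logistic = data.frame(C = 10^seq(-3, 3, length.out = 10)),
    decision_tree = expand.grid(min_samples_split = c(10L, 20L),
                                min_samples_leaf = c(5L, 10L),
                                criterion = c("gini", "information"),
                                stringsAsFactors = FALSE),
    bagged_trees = expand.grid(B = c(25L, 50L),
                               min_samples_split = c(10L, 20L),
                               min_samples_leaf = c(5L, 10L),
                               stringsAsFactors = FALSE),
    random_forest = expand.grid(B = 200L,
                                m = c("sqrt", "log2"),
                                min_samples_leaf = c(1L, 5L),
                                stringsAsFactors = FALSE),
    gradient_boosted_trees = expand.grid(max_depth = c(2L, 3L),
                                         l2_regularization = c(0, 1),
                                         stringsAsFactors = FALSE),
    stop("unknown family: ", family))
}

# L1-penalised class-weighted logistic regression, parameterised by the
# inverse penalty C so the objective is sum_i w_i loss_i + ||beta||_1 / C.
# Weights are normalised to mean 1 and lambda set to 1/(C * sum(w)); with
# glmnet's (1/n) * sum(w_i l_i) + lambda * ||beta||_1 convention this makes
# the fit exactly invariant to duplicating samples while halving their
# weights. Standardisation happens upstream, never here.
# With every predictor constant the L1 optimum is the weighted-MLE
# intercept with all slopes zero; glmnet refuses that input, so short-cut.
.all_constant <- function(x) {
  all(apply(x, 2, function(col) max(col) - min(col) == 0))
}

.intercept_only_coefs <- function(x, y, w) {
  p <- sum(w * y) / sum(w)
  cf <- c(stats::qlogis(min(max(p, 1e-12), 1 - 1e-12)), rep(0, ncol(x)))
  names(cf) <- c("(Intercept)", colnames(x))
  cf
}

.fit_sparse_logistic <- function(x, y, C, w) {
  if (.all_constant(x)) return(.intercept_only_coefs(x, y, w))
  sw <- sum(w)
  fit <- glmnet::glmnet(x, y, family = "binomial",
                        weights = w * length(y) / sw,
                        lambda = 1 / (C * sw),
                        standardize = FALSE, thresh = 1e-10, maxit = 1e6)
  cf <- as.numeric(stats::coef(fit))
  names(cf) <- c("(Intercept)", colnames(x))
  cf
}

# Fit the whole C grid in one glmnet path call (decreasing lambda).
.fit_sparse_logistic_path <- function(x, y, C_grid, w) {
  if (.all_constant(x)) {
    cf <- .intercept_only_coefs(x, y, w)
    return(matrix(cf, length(cf), length(C_grid),
                  dimnames = list(names(cf), NULL)))
  }
  sw <- sum(w)
  lambda <- 1 / (C_grid * sw)
  ord <- order(lambda, decreasing = TRUE)
  fit <- glmnet::glmnet(x, y, family = "binomial",
                        weights = w * length(y) / sw,
                        lambda = lambda[ord],
                        standardize = FALSE, thresh = 1e-10, maxit = 1e6)
  cf <- as.matrix(stats::coef(fit))  # (p+1) x length(grid), path order
  out <- matrix(NA_real_, nrow(cf), length(C_grid),
                dimnames = list(c("(Intercept)", colnames(x)), NULL))
  out[, ord] <- cf
  out
}

.logistic_prob <- function(coefs, x) {
  stats::plogis(drop(cbind(1, x) %*% coefs))
}

.rpart_control <- function(hyper) {
  rpart::rpart.control(minsplit = hyper$min_samples_split %||% 20L,
                       minbucket = hyper$min_samples_leaf %||% 7L,
                       cp = 0.001, xval = 0, maxsurrogate = 0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.fit_tree <- function(x, y, hyper, w) {
  df <- data.frame(.y = factor(y, levels = c(0, 1)), x, check.names = FALSE)
  parms <- list(split = if ((hyper$criterion %||% "gini") == "information")
    "information" else "gini")
  rpart::rpart(.y ~ ., data = df, weights = w, method = "class",
               parms = parms, control = .rpart_control(hyper))
}

.predict_tree <- function(fit, x) {
  stats::predict(fit, data.frame(x, check.names = FALSE), type = "prob")[, "1"]
}

#' Fit a learner
#'
#' Uniform interface over the supported families: fit on a numeric matrix
#' with per-sample weights and one hyperparameter combination, return an
#' object whose probabilities come from [predict_prob()]. Bagging draws `B`
#' bootstrap resamples of the training rows, fits the base tree on each and
#' averages the `B` predicted probabilities.
#'
#' @param family learner family, see [model_spec()].
#' @param x numeric feature matrix (standardised upstream).
#' @param y binary 0/1 outcome vector.
#' @param hyper one-row data.frame (a row of the family's hyper grid).
#' @param weights per-sample weights (default all 1).
#' @return object of class `ppgdm_fit`.
#' @export
fit_learner <- function(family, x, y, hyper, weights = NULL) {
  w <- if (is.null(weights)) rep(1, length(y)) else weights
  obj <- switch(family,
    sparse_logistic = list(coefs = .fit_sparse_logistic(x, y, hyper$C, w)),
    decision_tree = list(fit = .fit_tree(x, y, hyper, w)),
    bagged_trees = {
      B <- hyper$B %||% 25L
      fits <- lapply(seq_len(B), function(b) {
        idx <- sample.int(length(y), replace = TRUE)
        .fit_tree(x[idx, , drop = FALSE], y[idx], hyper, w[idx])
      })
      list(fits = fits)
    },
    random_forest = {
      mtry <- switch(hyper$m %||% "sqrt",
                     sqrt = max(1L, floor(sqrt(ncol(x)))),
                     log2 = max(1L, floor(log2(ncol(x)))))
      cw <- class_weights(y)
      list(fit = randomForest::randomForest(
        x, factor(y, levels = c(0, 1)), ntree = hyper$B %||% 200L,
        mtry = mtry, nodesize = hyper$min_samples_leaf %||% 1L,
        classwt = cw / sum(cw)))
    },
    gradient_boosted_trees = {
      dtrain <- xgboost::xgb.DMatrix(x, label = y, weight = w)
      list(fit = xgboost::xgb.train(
        params = list(objective = "binary:logistic",
                      max_depth = hyper$max_depth %||% 3L,
                      lambda = hyper$l2_regularization %||% 1,
                      eta = 0.1, nthread = 1),
        data = dtrain, nrounds = 100L, verbose = 0))
    },
    stop("unknown family: ", family))
  structure(c(obj, list(family = family, hyper = hyper)), class = "ppgdm_fit")
}

#' Predict class-1 probabilities from a fitted learner
#'
#' @param fit a `ppgdm_fit` from [fit_learner()].
#' @param x numeric feature matrix on the training scale.
#' @return vector of probabilities.
#' @export
predict_prob <- function(fit, x) {
  stopifnot(inherits(fit, "ppgdm_fit"))
  switch(fit$family,
    sparse_logistic = .logistic_prob(fit$coefs, x),
    decision_tree = .predict_tree(fit$fit, x),
    bagged_trees = rowMeans(matrix(unlist(lapply(fit$fits, .predict_tree, x = x)),
                                   nrow = nrow(x))),
    random_forest = stats::predict(fit$fit, x, type = "prob")[, "1"],
    gradient_boosted_trees = stats::predict(fit$fit, xgboost::xgb.DMatrix(x)))
}

#' Selected features of a fitted learner
#'
#' For the sparse logistic family: the predictors with nonzero coefficients.
#' Tree families select implicitly; NULL is returned.
#'
#' @param fit a `ppgdm_fit`.
#' @return character vector or NULL.
#' @export
selected_features <- function(fit) {
  if (fit$family != "sparse_logistic") return(NULL)
  cf <- fit$coefs[-1]
  names(cf)[cf != 0]
}
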