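test_that("ROC and AUC match hand-computed and boundary cases", {
  expect_equal(roc_auc(toy_preds(c(0.9, 0.4, 0.6, 0.2), c(1, 1, 0, 0)))$auc, 0.75)
  expect_equal(roc_auc(toy_preds(c(0.9, 0.8, 0.3, 0.1), c(1, 1, 0, 0)))$auc, 1.0)
  expect_equal(roc_auc(toy_preds(rep(0.5, 6), c(1, 1, 1, 0, 0, 0)))$auc, 0.5)
  expect_error(roc_auc(toy_preds(c(0.4, 0.6), c(1, 1))), "both classes")

  roc <- roc_auc(toy_preds(c(0.9, 0.4, 0.6, 0.6, 0.2), c(1, 1, 0, 1, 0)))
  expect_true(all(diff(roc$points$tpr) >= 0))
  expect_true(all(diff(roc$points$fpr) >= 0))
})

test_that("trapezoidal AUC equals the pairwise concordance oracle", {
  set.seed(11)
  for (i in 1:25) {
    n <- sample(10:200, 1)
    y <- rbinom(n, 1, runif(1, 0.15, 0.85))
    if (length(unique(y)) < 2) next
    prob <- round(runif(n), sample(c(1, 2, 6), 1))  # coarse rounding forces ties
    expect_equal(roc_auc(toy_preds(prob, y))$auc, auc_oracle(prob, y),
                 tolerance = 1e-12)
  }
})

test_that("Brier score matches closed forms", {
  expect_equal(brier(toy_preds(c(1, 1, 0), c(1, 1, 0))), 0)
  expect_equal(brier(toy_preds(rep(0.5, 4), c(1, 0, 1, 0))), 0.25)
  expect_equal(brier(toy_preds(c(0.8, 0.4), c(1, 0))), 0.10)
})

test_that("stratified folds balance classes and respect the seed", {
  y <- c(rep(1, 9), rep(0, 27))
  f <- stratified_folds(y, 4, seed = 2)
  expect_equal(sort(unique(f)), 1:4)
  for (k in 1:4) {
    expect_gte(sum(y == 1 & f == k), 2)
    # per-class counts differ by at most one across folds
    expect_lte(abs(sum(y == 0 & f == k) - 27 / 4), 1)
  }
  expect_identical(stratified_folds(y, 4, seed = 2), f)
  expect_error(stratified_folds(c(1, 0, 0, 0, 0), 4), "stratified")
})

test_that("nested CV separates well-separated clouds and records bookkeeping", {
  set.seed(12)
  n <- 60
  tab <- generate_cohort(generator_spec(n = n, seed = 12,
                                        outcome_model = "class_conditional"))
  y <- outcome_binary(tab)
  # overwrite the two predictors with 5-sigma-separated clouds
  tab$a_fg <- rnorm(n, 5, 1) + 5 * y
  tab$a_hba1c <- rnorm(n, 35, 1) + 5 * y
  preds <- nested_cv_evaluate(tab, model_spec("sparse_logistic"),
                              cv_config(seed = 1),
                              features = c("a_fg", "a_hba1c"))
  expect_gte(roc_auc(preds)$auc, 0.98)
  expect_equal(nrow(preds), n)
  expect_false(anyDuplicated(preds$id) > 0)
  expect_true(all(is.finite(preds$prob)))
  expect_length(attr(preds, "fold_hyper"), n)

  stab <- feature_stability(preds)
  expect_true(all(stab$fraction >= 0 & stab$fraction <= 1))
  expect_true(all(stab$count <= n))
  expect_setequal(stab$feature, c("a_fg", "a_hba1c"))
})

test_that("preprocessing statistics are fold-local (leakage canary)", {
  tab <- generate_cohort(generator_spec(n = 50, seed = 21,
                                        missing_rate = 0.1))
  x <- build_feature_matrix(tab, c("a_fg", "a_hba1c", "bmi", "age"))
  i <- 17
  x_pert <- x
  x_pert[i, "a_fg"] <- x_pert[i, "a_fg"] * 1e6

  # imputer and scaler fitted on the other rows are untouched by the
  # perturbation of the held-out row
  base <- mice_impute(x[-i, , drop = FALSE], x[i, , drop = FALSE])
  pert <- mice_impute(x_pert[-i, , drop = FALSE], x_pert[i, , drop = FALSE])
  expect_identical(base$train, pert$train)
  expect_identical(fit_scaler(base$train), fit_scaler(pert$train))

  # and the held-out row is scaled by training statistics, so its own
  # prediction (alone) responds to the perturbation
  sc <- fit_scaler(base$train)
  z_base <- apply_scaler(sc, base$apply_to)
  z_pert <- apply_scaler(sc, pert$apply_to)
  expect_gt(abs(z_pert[1, "a_fg"] - z_base[1, "a_fg"]), 1e3)
})

test_that("grid-search ties break toward the first grid entry", {
  set.seed(13)
  n <- 40
  tab <- generate_cohort(generator_spec(n = n, seed = 13))
  # exactly constant features: every C candidate scores identically in the
  # inner CV, so the declared-order tie-break decides
  tab$flat1 <- rep(1.0, n)
  tab$flat2 <- rep(2.0, n)
  preds <- nested_cv_evaluate(tab, model_spec("sparse_logistic"),
                              cv_config(outer = "stratified_kfold",
                                        outer_k = 2, seed = 1),
                              features = c("flat1", "flat2"))
  grid <- default_hyper_grid("sparse_logistic")
  for (h in attr(preds, "fold_hyper")) {
    expect_equal(h$C, grid$C[1])
  }
})
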