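#' Fit the deployment risk model on the full data
#'
#' The final model: impute and standardise on all labelled rows, choose the
#' penalty by inner stratified k-fold on the full data (the same grid-search
#' rule as inside the nested CV), refit on every row, and back-transform the
#' coefficients from the standardised scale to raw predictor units —
#' `b_raw = b_std / sd`, with the intercept adjusted by
#' `sum(b_std * mean / sd)` — so the score applies directly to raw
#' measurements (mmol/L, mmol/mol).
#'
#' @param table a labelled [cohort_table()].
#' @param model a [model_spec()] of family `sparse_logistic`.
#' @param cv a [cv_config()] (inner settings and seed are used).
#' @param features predictor columns; default the two-variable score
#'   `{a_fg, a_hba1c}`.
#' @return object of class `fitted_risk_model`: `intercept`, named
#'   `coefficients` on the raw scale, `std` (standardised-scale coefficients
#'   and scaler) and `provenance` (chosen penalty, seed, features).
#' @export
fit_final_model <- function(table, model = model_spec("sparse_logistic"),
                            cv = cv_config(),
                            features = c("a_fg", "a_hba1c")) {
  if (model$family != "sparse_logistic") {
    stop("the deployment risk score is a sparse logistic model")
  }
  y_all <- outcome_binary(table)
  keep <- !is.na(y_all)
  y <- y_all[keep]
  if (length(unique(y)) < 2) stop("both outcome classes must be present")
  x_raw <- build_feature_matrix(table[keep, , drop = FALSE], features)
  imp <- mice_impute(x_raw, iterations = cv$mice_iterations)
  sc <- fit_scaler(imp$train)
  x <- apply_scaler(sc, imp$train)

  set.seed(cv$seed)
  inner_seed <- sample.int(.Machine$integer.max - 1L, 1)
  best <- .inner_grid_search(x, y, model, cv, inner_seed)
  C <- model$hyper_grid$C[best]
  w <- if (model$class_weighting) .sample_weights(y, class_weights(y)) else rep(1, length(y))
  cf <- .fit_sparse_logistic(x, y, C, w)

  b_std <- cf[-1]
  b_raw <- b_std / sc$scale
  b0_raw <- cf[1] - sum(b_std * sc$center / sc$scale)
  structure(list(intercept = unname(b0_raw),
                 coefficients = b_raw,
                 std = list(intercept = unname(cf[1]), coefficients = b_std,
                            center = sc$center, scale = sc$scale),
                 provenance = list(family = model$family, C = C,
                                   seed = cv$seed,
                                   inner_folds = cv$inner_folds,
                                   inner_metric = cv$inner_metric,
                                   features = colnames(x_raw))),
            class = "fitted_risk_model")
}

#' Reference two-variable composite risk model
#'
#' The deployment composite risk score for postpartum prediabetes after
#' GDM on raw antenatal measurements:
#' `P = 1 / (1 + exp(-(-8.36 + 0.58 * a_fg + 0.10 * a_hba1c)))`, with
#' fasting glucose in mmol/L and HbA1c in mmol/mol.
#'
#' @return a `fitted_risk_model`.
#' @export
reference_risk_model <- function() {
  structure(list(intercept = -8.36,
                 coefficients = c(a_fg = 0.58, a_hba1c = 0.10),
                 std = NULL,
                 provenance = list(family = "sparse_logistic",
                                   source = "reference coefficients")),
            class = "fitted_risk_model")
}

#' Composite risk probability
#'
#' `1 / (1 + exp(-b))` with `b = b0 + sum(b_m x_m)` over the model's named
#' raw-scale predictors; strictly increasing in every predictor with a
#' positive coefficient.
#'
#' @param model a `fitted_risk_model`.
#' @param newdata data.frame (or named list / named vector) containing every
#'   predictor named in the model; unknown names are an error.
#' @return vector of probabilities.
#' @export
composite_risk <- function(model, newdata) {
  stopifnot(inherits(model, "fitted_risk_model"))
  if (is.numeric(newdata) && !is.null(names(newdata))) {
    newdata <- as.data.frame(as.list(newdata))
  }
  need <- names(model$coefficients)
  absent <- setdiff(need, names(newdata))
  if (length(absent) > 0) {
    stop("predictor(s) missing from newdata: ", paste(absent, collapse = ", "))
  }
  X <- as.matrix(as.data.frame(newdata)[, need, drop = FALSE])
  if (any(!is.finite(X))) stop("predictor values must be finite")
  stats::plogis(model$intercept + drop(X %*% model$coefficients))
}

#' Serialise / restore a fitted risk model
#'
#' JSON round-trip of the intercept, named coefficients and provenance.
#'
#' @param model a `fitted_risk_model`.
#' @param path output path.
#' @return `path` invisibly; `read_risk_model()` returns the model.
#' @export
write_risk_model <- function(model, path) {
  stopifnot(inherits(model, "fitted_risk_model"))
  obj <- list(intercept = model$intercept,
              coefficients = as.list(model$coefficients),
              provenance = model$provenance)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_risk_model
#' @export
read_risk_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(intercept = obj$intercept,
                 coefficients = unlist(obj$coefficients),
                 std = NULL, provenance = obj$provenance),
            class = "fitted_risk_model")
}

#' Operating points at predetermined sensitivities
#'
#' For each target sensitivity (in percent), selects the cut-point as the
#' largest candidate (0 or an observed score) at which the proportion of
#' positive scores strictly above it still meets the target — so a 100%
#' target lands strictly below the minimum positive score — and reports the
#' full [threshold_metrics()] row there (classification rule `prob >= c`).
#' Achieved sensitivity is non-decreasing as the target decreases.
#'
#' @param preds an `aggregated_predictions` object.
#' @param sensitivities targets in percent, default c(60, 70, 75, 80, 90).
#' @return data.frame of metric rows with a `target_sensitivity` column.
#' @export
operating_points <- function(preds, sensitivities = c(60, 70, 75, 80, 90)) {
  if (any(sensitivities < 0 | sensitivities > 100)) {
    stop("target sensitivities must lie in [0, 100]")
  }
  if (length(unique(preds$label)) < 2) stop("both classes must be present")
  pos_scores <- preds$prob[preds$label == 1]
  cand <- sort(unique(c(0, preds$prob)))
  rows <- lapply(sensitivities, function(target) {
    ok <- vapply(cand, function(cc) mean(pos_scores > cc) >= target / 100,
                 logical(1))
    cc <- if (any(ok)) max(cand[ok]) else 0
    row <- as.data.frame(threshold_metrics(preds, cc))
    cbind(target_sensitivity = target, row)
  })
  do.call(rbind, rows)
}
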