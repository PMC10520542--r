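#' Build a numeric feature matrix from a cohort table
#'
#' Numeric covariates pass through; categorical covariates are one-hot
#' encoded with the first level as reference; logical flags become 0/1.
#' Missing cells stay NA (the imputation step fills them).
#'
#' @param table a [cohort_table()].
#' @param features cohort column names to include; default all antenatal and
#'   delivery covariates.
#' @return numeric matrix with named columns (dummies named
#'   `feature.level`).
#' @export
build_feature_matrix <- function(table, features = antenatal_features(TRUE)) {
  missing_cols <- setdiff(features, names(table))
  if (length(missing_cols) > 0) {
    stop("features not in table: ", paste(missing_cols, collapse = ", "))
  }
  cols <- list()
  for (f in features) {
    v <- table[[f]]
    if (is.factor(v) || is.character(v)) {
      lev <- if (is.factor(v)) levels(v) else sort(unique(v[!is.na(v)]))
      for (l in lev[-1]) {
        d <- as.numeric(v == l)
        d[is.na(v)] <- NA
        cols[[paste(f, l, sep = ".")]] <- d
      }
    } else if (is.logical(v)) {
      cols[[f]] <- as.numeric(v)
    } else {
      cols[[f]] <- as.numeric(v)
    }
  }
  do.call(cbind, cols)
}

#' Chained-equations imputation
#'
#' Fold-local single imputation by chained equations: missing cells are
#' initialised at the training-set feature means, then features are cycled
#' for `iterations` sweeps; each sweep regresses a feature on all the others
#' by ordinary least squares over the training rows observed for that
#' feature and replaces its missing cells (in both matrices) with the
#' fitted values. All models are fitted on `train` rows only and then
#' applied to `apply_to` rows, so no information flows from held-out data.
#' One-hot dummy columns are clipped to [0, 1] after each sweep. The scheme
#' has no internal randomness: `seed` is accepted for interface symmetry and
#' recorded but unused, and the result is invariant to the row order of
#' `train`.
#'
#' @param train numeric matrix (rows = training samples) with NAs.
#' @param apply_to optional matrix with the same columns to complete using
#'   the training-fitted models.
#' @param iterations number of sweeps (>= 1), default 10.
#' @param seed recorded, unused (deterministic scheme).
#' @return list with completed `train` and `apply_to` matrices.
#' @export
mice_impute <- function(train, apply_to = NULL, iterations = 10, seed = NULL) {
  stopifnot(is.matrix(train), iterations >= 1)
  p <- ncol(train)
  nm <- colnames(train)
  n_obs <- colSums(!is.na(train))
  if (any(n_obs == 0)) {
    stop("feature(s) with no observed training values: ",
         paste(nm[n_obs == 0], collapse = ", "))
  }
  is_dummy <- vapply(seq_len(p), function(j) {
    v <- train[!is.na(train[, j]), j]
    all(v %in% c(0, 1))
  }, logical(1))

  tr_miss <- is.na(train)
  ap_miss <- if (!is.null(apply_to)) is.na(apply_to) else NULL
  mu <- colMeans(train, na.rm = TRUE)
  tr <- train
  ap <- apply_to
  for (j in seq_len(p)) {
    tr[tr_miss[, j], j] <- mu[j]
    if (!is.null(ap)) ap[ap_miss[, j], j] <- mu[j]
  }
  if (!any(tr_miss) && (is.null(ap) || !any(ap_miss))) {
    return(list(train = tr, apply_to = ap))
  }

  needs <- which(colSums(tr_miss) > 0 |
                   (if (is.null(ap)) 0 else colSums(ap_miss)) > 0)
  for (it in seq_len(iterations)) {
    for (j in needs) {
      obs <- !tr_miss[, j]
      X <- cbind(1, tr[obs, -j, drop = FALSE])
      fit <- stats::lm.fit(X, tr[obs, j])
      beta <- fit$coefficients
      beta[is.na(beta)] <- 0
      if (any(tr_miss[, j])) {
        Xm <- cbind(1, tr[tr_miss[, j], -j, drop = FALSE])
        v <- drop(Xm %*% beta)
        if (is_dummy[j]) v <- pmin(pmax(v, 0), 1)
        tr[tr_miss[, j], j] <- v
      }
      if (!is.null(ap) && any(ap_miss[, j])) {
        Xa <- cbind(1, ap[ap_miss[, j], -j, drop = FALSE])
        v <- drop(Xa %*% beta)
        if (is_dummy[j]) v <- pmin(pmax(v, 0), 1)
        ap[ap_miss[, j], j] <- v
      }
    }
  }
  list(train = tr, apply_to = ap)
}

#' Fit a training-set standardiser
#'
#' Learns per-feature mean and SD on training rows only. Constant features
#' get scale 1 and are flagged, so they standardise to all zeros rather than
#' NaN.
#'
#' @param train numeric matrix (>= 2 rows), no missing values.
#' @return object of class `ppgdm_scaler` with `center`, `scale`,
#'   `constant` (logical per feature).
#' @export
fit_scaler <- function(train) {
  stopifnot(is.matrix(train), nrow(train) >= 2)
  center <- colMeans(train)
  scale <- apply(train, 2, stats::sd)
  constant <- !is.finite(scale) | scale < 1e-12
  scale[constant] <- 1
  structure(list(center = center, scale = scale, constant = constant),
            class = "ppgdm_scaler")
}

#' Apply a fitted standardiser
#'
#' @param params a `ppgdm_scaler` from [fit_scaler()].
#' @param m numeric matrix with the same columns as the training matrix.
#' @return z-scored matrix `(m - center) / scale`.
#' @export
apply_scaler <- function(params, m) {
  stopifnot(inherits(params, "ppgdm_scaler"), is.matrix(m),
            ncol(m) == length(params$center))
  sweep(sweep(m, 2, params$center, "-"), 2, params$scale, "/")
}

#' Balanced class weights
#'
#' The balancing rule `w_k = 1 / (2 * fraction of samples in class k)`, which
#' equalises the total loss mass of the two classes: `n_0 w_0 = n_1 w_1 =
#' n / 2`.
#'
#' @param labels binary vector (0/1, logical, or two-level factor).
#' @return named numeric vector `c("0" = w_0, "1" = w_1)`.
#' @export
class_weights <- function(labels) {
  y <- as.integer(as.factor(labels)) - 1L
  if (length(unique(y[!is.na(y)])) < 2) {
    stop("class_weights requires both classes to be present")
  }
  f1 <- mean(y == 1L)
  w <- c("0" = 1 / (2 * (1 - f1)), "1" = 1 / (2 * f1))
  w
}

# Expand per-class weights to a per-sample weight vector.
.sample_weights <- function(y, weights = NULL) {
  if (is.null(weights)) return(rep(1, length(y)))
  unname(weights[as.character(as.integer(y))])
}
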