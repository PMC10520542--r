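#' Decision curve analysis
#'
#' Net benefit of acting on the model at each threshold probability `pt`:
#' classify positive at `prob >= pt` and compute
#' `nb_model = (TP - FP * pt / (1 - pt)) / N`, against the treat-all
#' comparator `nb_all = (P - (N - P) * pt / (1 - pt)) / N` and treat-none
#' (`nb_none = 0`). `N` defaults to the prediction-set size but is
#' configurable (e.g. to the size of the full cohort from which the
#' prediction set was drawn).
#'
#' @param preds an `aggregated_predictions` object.
#' @param pt_grid threshold probabilities, each in (0, 1); default 0.01 to
#'   0.99 in steps of 0.01.
#' @param n_total denominator N; default `nrow(preds)`.
#' @return data.frame with columns pt, nb_model, nb_all, nb_none.
#' @export
net_benefit <- function(preds, pt_grid = seq(0.01, 0.99, by = 0.01),
                        n_total = NULL) {
  if (any(pt_grid <= 0 | pt_grid >= 1)) {
    stop("threshold probabilities must lie strictly inside (0, 1)")
  }
  if (length(unique(preds$label)) < 2) stop("both classes must be present")
  N <- if (is.null(n_total)) nrow(preds) else n_total
  P <- sum(preds$label == 1); Neg <- sum(preds$label == 0)
  rows <- lapply(pt_grid, function(pt) {
    pos <- preds$prob >= pt
    tp <- sum(pos & preds$label == 1)
    fp <- sum(pos & preds$label == 0)
    odds <- pt / (1 - pt)
    data.frame(pt = pt,
               nb_model = (tp - fp * odds) / N,
               nb_all = (P - Neg * odds) / N,
               nb_none = 0)
  })
  do.call(rbind, rows)
}

#' Cohen's d with pooled standard deviation
#'
#' `(mu1 - mu2) / s_pooled`, `s_pooled^2 = ((n1-1) sd1^2 + (n2-1) sd2^2) /
#' (n1 + n2 - 2)`; the sign follows `mu1 - mu2`.
#'
#' @param mu1,sd1,n1 mean, SD and size of the first sample.
#' @param mu2,sd2,n2 mean, SD and size of the second sample.
#' @return effect size (standardised mean difference).
#' @export
cohens_d <- function(mu1, sd1, n1, mu2, sd2, n2) {
  if (n1 < 2 || n2 < 2) stop("both groups need n >= 2")
  if (sd1 <= 0 || sd2 <= 0) stop("SDs must be positive")
  s2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
  (mu1 - mu2) / sqrt(s2)
}

# Power of the two-sided two-sample t-test at real-valued group sizes,
# via the noncentral t distribution.
.t2_power <- function(n1, d, ratio, alpha) {
  n2 <- ratio * n1
  df <- n1 + n2 - 2
  ncp <- abs(d) / sqrt(1 / n1 + 1 / n2)
  tc <- stats::qt(1 - alpha / 2, df)
  stats::pt(-tc, df, ncp) + 1 - stats::pt(tc, df, ncp)
}

#' Power-analysis specification
#'
#' @param d Cohen's effect size (> 0).
#' @param alpha two-sided significance level, in (0, 1).
#' @param power target power, in (0, 1).
#' @param ratio allocation ratio n2/n1 (> 0).
#' @return object of class `power_spec`.
#' @export
power_spec <- function(d, alpha = 0.05, power = 0.90, ratio = 1) {
  stopifnot(d > 0, alpha > 0, alpha < 1, power > 0, power < 1, ratio > 0)
  structure(list(d = d, alpha = alpha, power = power, ratio = ratio),
            class = "power_spec")
}

#' Minimum sample size for a two-sample t-test
#'
#' Solves the noncentral-t power equation for the smallest real `n1` such
#' that the two-sided test at level `alpha`, with `n2 = ratio * n1`, reaches
#' the target power at effect size `d`; each group is then rounded up
#' independently.
#'
#' @param spec a [power_spec()].
#' @return list with integer `n1`, `n2`, `total`, and the unrounded
#'   `n1_exact`.
#' @export
solve_sample_size <- function(spec) {
  stopifnot(inherits(spec, "power_spec"))
  # df = n1 (1 + ratio) - 2 must stay positive on the search interval
  lo <- 2.5 / (1 + spec$ratio)
  f <- function(n1) .t2_power(n1, spec$d, spec$ratio, spec$alpha) - spec$power
  hi <- 10
  while (f(hi) < 0 && hi < 1e9) hi <- hi * 10
  if (f(hi) < 0) stop("target power unattainable at this effect size")
  n1 <- if (f(lo) >= 0) lo else stats::uniroot(f, c(lo, hi), tol = 1e-9)$root
  list(n1 = ceiling(n1), n2 = ceiling(spec$ratio * n1),
       total = ceiling(n1) + ceiling(spec$ratio * n1), n1_exact = n1)
}

#' Power curve over a grid of sample sizes, effect sizes and levels
#'
#' Noncentral-t power of the two-sided two-sample t-test at every
#' combination of the supplied grids; monotone increasing in `n1` and in `d`
#' at fixed `alpha`.
#'
#' @param n1 vector of first-group sizes.
#' @param d vector of effect sizes.
#' @param alpha vector of significance levels.
#' @param ratio allocation ratio n2/n1.
#' @return data.frame with columns n1, n2, d, alpha, power.
#' @export
power_curve <- function(n1, d, alpha = 0.05, ratio = 1) {
  grid <- expand.grid(n1 = n1, d = d, alpha = alpha)
  grid$n2 <- ratio * grid$n1
  grid$power <- mapply(.t2_power, n1 = grid$n1, d = grid$d,
                       alpha = grid$alpha, MoreArgs = list(ratio = ratio))
  grid[, c("n1", "n2", "d", "alpha", "power")]
}
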