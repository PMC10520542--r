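# Information-theoretic evaluation of a dichotomised risk score. At a
# cut-point c the sensitivity g1(c) and specificity g2(c) define two
# Bernoulli response distributions — the diseased population responds
# positive with probability g1, the non-diseased with probability 1 - g2 —
# and the K-L divergences between them quantify rule-in and rule-out
# potential.

# Probabilities entering any log are clamped to [eps, 1-eps]; the cut-point
# grid inevitably hits g1 or g2 in {0,1} at extreme c, where divergences are
# reported as the large finite clamped value and flagged, never +/-Inf.
.clamp <- function(p, eps = 1e-12) pmin(pmax(p, eps), 1 - eps)

.check_unit <- function(x, what) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    stop(what, " must lie in [0, 1]")
  }
}

#' Rule-in and rule-out K-L divergences
#'
#' `kl_in(g1, g2)` is the divergence of the diseased response distribution
#' from the non-diseased one, `g1 ln(g1 / (1 - g2)) + (1 - g1) ln((1 - g1) /
#' g2)` — high values mean a positive result strongly rules the disease in.
#' `kl_out` is the reverse divergence, governing rule-out strength. Both are
#' nonnegative and are jointly zero iff `g1 + g2 = 1` (an uninformative
#' test). Vectorised; arguments at 0 or 1 are handled by clamping.
#'
#' @param g1 sensitivity in [0, 1].
#' @param g2 specificity in [0, 1].
#' @return divergence in nats.
#' @export
kl_in <- function(g1, g2) {
  .check_unit(g1, "g1"); .check_unit(g2, "g2")
  a <- .clamp(g1); b <- .clamp(1 - g2)
  # analytically >= 0; guard against -1e-17 float noise near the zero line
  pmax(a * log(a / b) + (1 - a) * log((1 - a) / (1 - b)), 0)
}

#' @rdname kl_in
#' @export
kl_out <- function(g1, g2) {
  .check_unit(g1, "g1"); .check_unit(g2, "g2")
  kl_in(1 - g2, 1 - g1)
}

#' Pre-to-post-test odds multiplier
#'
#' `e^D`: for the rule-in divergence this is the factor by which the disease
#' odds of a randomly selected diseased individual increase after testing
#' (and the rule-out analogue for a non-diseased individual). Always >= 1
#' for a nonnegative divergence.
#'
#' @param d K-L divergence in nats (>= 0).
#' @return odds ratio `exp(d)`.
#' @export
pin_pout <- function(d) {
  if (any(!is.finite(d)) || any(d < 0)) stop("divergence must be >= 0")
  exp(d)
}

#' Information distinguishability
#'
#' `1 - e^(-D)`, a [0, 1) rescaling of a divergence: 0 for an uninformative
#' test, approaching 1 as the two response distributions separate.
#'
#' @param d K-L divergence in nats (>= 0).
#' @return proportion in [0, 1).
#' @export
info_distinguishability <- function(d) {
  if (any(!is.finite(d)) || any(d < 0)) stop("divergence must be >= 0")
  1 - exp(-d)
}

#' Divergence-derived metrics from sensitivity and specificity
#'
#' All the information-theoretic columns of a threshold-metrics row computed
#' directly from (g1, g2): both divergences, their sum, the odds multipliers,
#' the distinguishability indices and the Youden index.
#'
#' @param g1,g2 sensitivity and specificity in [0, 1] (vectorised).
#' @return data.frame with columns kl_in, kl_out, tkl, p_in, p_out, id_in,
#'   id_out, youden.
#' @export
divergence_metrics <- function(g1, g2) {
  din <- kl_in(g1, g2); dout <- kl_out(g1, g2)
  data.frame(kl_in = din, kl_out = dout, tkl = din + dout,
             p_in = pin_pout(din), p_out = pin_pout(dout),
             id_in = info_distinguishability(din),
             id_out = info_distinguishability(dout),
             youden = g1 + g2 - 1)
}

#' Full metric row at one probability cut-point
#'
#' Classifies positive at `prob >= c` (ties positive) and reports the
#' complete row: sensitivity g1, specificity g2, PPV, NPV, F1, accuracy,
#' Youden J, both K-L divergences and their sum, odds multipliers,
#' distinguishability indices, and `ta` — the integer-rounded percent of the
#' cohort scoring strictly below c (the fraction in whom testing can be
#' avoided at that threshold). PPV and F1 are NA when no sample is predicted
#' positive. A `degenerate` flag marks rows where g1 or g2 hits 0 or 1, so
#' clamped divergences can be recognised.
#'
#' @param preds an `aggregated_predictions` object (or data.frame with
#'   `prob` and `label`).
#' @param c probability cut-point in [0, 1].
#' @return one-row data.frame (class `threshold_metrics_row`).
#' @export
threshold_metrics <- function(preds, c) {
  stopifnot(length(c) == 1, c >= 0, c <= 1)
  y <- preds$label; s <- preds$prob
  if (length(unique(y)) < 2) stop("both classes must be present")
  pos <- s >= c
  tp <- sum(pos & y == 1); fp <- sum(pos & y == 0)
  fn <- sum(!pos & y == 1); tn <- sum(!pos & y == 0)
  g1 <- tp / (tp + fn); g2 <- tn / (tn + fp)
  ppv <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  npv <- if (tn + fn > 0) tn / (tn + fn) else NA_real_
  f1 <- if (!is.na(ppv) && (ppv + g1) > 0) 2 * ppv * g1 / (ppv + g1) else NA_real_
  acc <- (tp + tn) / length(y)
  dm <- divergence_metrics(g1, g2)
  out <- data.frame(c = c, g1 = g1, g2 = g2, ppv = ppv, npv = npv, f1 = f1,
                    accuracy = acc, youden = dm$youden,
                    kl_in = dm$kl_in, kl_out = dm$kl_out, tkl = dm$tkl,
                    p_in = dm$p_in, p_out = dm$p_out,
                    id_in = dm$id_in, id_out = dm$id_out,
                    ta = round(100 * mean(s < c)),
                    degenerate = g1 %in% c(0, 1) || g2 %in% c(0, 1))
  class(out) <- c("threshold_metrics_row", "data.frame")
  out
}

#' Scan cut-points and select the rule-in / rule-out / combined tests
#'
#' Evaluates [threshold_metrics()] at every grid point (default 1000 points,
#' 0.000 to 0.999 in steps of 0.001) and selects three diagnostic tests:
#' `c_in` maximising the rule-in divergence, `c_out` maximising the rule-out
#' divergence, and `c_in_out` maximising their sum (the symmetric total-K-L
#' objective). Ties break toward the smaller cut-point. If the score is
#' anti-informative (Youden index <= 0 at the combined optimum) the
#' selection is flagged.
#'
#' @param preds an `aggregated_predictions` object.
#' @param grid increasing vector of cut-points in [0, 1].
#' @return object of class `cutpoint_scan`: list with `rows` (the full
#'   metric table) and `selection` (c_in, d_in, c_out, d_out, c_in_out,
#'   tkl_max, youden_at_in_out, flagged).
#' @export
scan_cutpoints <- function(preds, grid = seq(0, 0.999, by = 0.001)) {
  rows <- do.call(rbind, lapply(grid, function(cc) {
    as.data.frame(threshold_metrics(preds, cc))
  }))
  # rows where g1 or g2 hits 0/1 carry clamped stand-ins for divergences that
  # are genuinely infinite (a structural zero of the estimated response
  # distribution, not usable information); they are excluded from the
  # selection unless the whole scan is degenerate
  eligible <- if (all(rows$degenerate)) rep(TRUE, nrow(rows)) else !rows$degenerate
  pick <- function(v) which(eligible)[which.max(v[eligible])]
  i_in <- pick(rows$kl_in)
  i_out <- pick(rows$kl_out)
  i_both <- pick(rows$tkl)
  sel <- list(c_in = rows$c[i_in], d_in = rows$kl_in[i_in],
              c_out = rows$c[i_out], d_out = rows$kl_out[i_out],
              c_in_out = rows$c[i_both], tkl_max = rows$tkl[i_both],
              youden_at_in_out = rows$youden[i_both],
              flagged = rows$youden[i_both] <= 0)
  structure(list(rows = rows, selection = sel), class = "cutpoint_scan")
}

#' Information graph of a diagnostic test
#'
#' For fixed (g1, g2), the diagnostic information carried by a positive and
#' a negative test result as a function of the pre-test probability
#' `x = Pr(D1)`: `i_plus` and `i_minus` are the K-L divergences of the
#' post-test (posterior) disease distribution from the pre-test (prior)
#' one, and their expectation `i_expected = Pr(T1) i_plus + (1 - Pr(T1))
#' i_minus` — the mutual information between disease status and test result
#' — with `Pr(T1) = x g1 + (1 - x)(1 - g2)`.
#'
#' @param g1,g2 sensitivity and specificity in (0, 1).
#' @param x_grid pre-test probabilities in (0, 1).
#' @return data.frame with columns x, pr_t1, i_plus, i_minus, i_expected.
#' @export
information_graph <- function(g1, g2, x_grid = seq(0.01, 0.99, by = 0.01)) {
  stopifnot(length(g1) == 1, length(g2) == 1, g1 > 0, g1 < 1, g2 > 0, g2 < 1)
  x <- .clamp(x_grid)
  pr_t1 <- x * g1 + (1 - x) * (1 - g2)
  post_pos <- .clamp(x * g1 / pr_t1)
  post_neg <- .clamp(x * (1 - g1) / (1 - pr_t1))
  kl_bern <- function(p, q) {
    p <- .clamp(p); q <- .clamp(q)
    p * log(p / q) + (1 - p) * log((1 - p) / (1 - q))
  }
  i_plus <- kl_bern(post_pos, x)
  i_minus <- kl_bern(post_neg, x)
  data.frame(x = x_grid, pr_t1 = pr_t1, i_plus = i_plus, i_minus = i_minus,
             i_expected = pr_t1 * i_plus + (1 - pr_t1) * i_minus)
}

#' Total K-L divergence as a discrete Bregman divergence
#'
#' The sum of the vertical distances between the negative Shannon entropy
#' function `h(p) = p ln p + (1 - p) ln(1 - p)` and its tangents at
#' `p = 1 - g2` (evaluated at g1) and at `p = g1` (evaluated at 1 - g2).
#' Analytically equal to `kl_in + kl_out`; nonnegative by convexity of `h`.
#'
#' @param g1,g2 sensitivity and specificity in (0, 1); vectorised.
#' @return total divergence in nats.
#' @export
bregman_total_kl <- function(g1, g2) {
  .check_unit(g1, "g1"); .check_unit(g2, "g2")
  a <- .clamp(g1); b <- .clamp(1 - g2)
  h <- function(p) p * log(p) + (1 - p) * log(1 - p)
  hp <- function(p) log(p / (1 - p))
  tangent <- function(p, at) h(at) + hp(at) * (p - at)
  (h(a) - tangent(a, b)) + (h(b) - tangent(b, a))
}
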