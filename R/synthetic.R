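# Class-conditional moments of the antenatal, delivery and postpartum
# characteristics of a UK multi-ethnic GDM audit cohort (n = 394 with known
# postpartum glucose status: 92 prediabetes, 302 normal glucose tolerance).
# "pos" = postpartum prediabetes, "neg" = postpartum NGT.
.cohort_moments <- data.frame(
  feature  = c("age", "height", "weight_implied", "bmi", "sbp", "dbp",
               "ga_ogtt", "a_fg", "a_pg", "a_hba1c", "ga_birth",
               "birth_weight", "p_fg", "p_pg", "p_hba1c"),
  mean_all = c(32.21, 1.64, 79.78, 29.76, 115.71, 69.98, 28.16, 4.95, 8.55,
               35.52, 37.91, 3211.95, 4.99, 5.59, 37.53),
  sd_all   = c(5.40, 0.07, 19.80, 6.81, 13.62, 9.40, 4.21, 0.87, 1.75,
               4.69, 1.27, 467.75, 0.62, 1.62, 4.84),
  mean_pos = c(32.38, 1.64, 84.32, 31.21, 116.07, 70.41, 27.50, 5.38, 8.90,
               38.13, 37.65, 3216.48, 5.64, 7.10, 42.22),
  sd_pos   = c(5.46, 0.07, 22.82, 7.40, 13.78, 8.18, 4.08, 0.91, 1.75,
               4.61, 1.28, 511.41, 0.79, 2.08, 4.56),
  mean_neg = c(32.16, 1.64, 78.36, 29.30, 115.60, 69.85, 28.37, 4.82, 8.44,
               34.72, 37.99, 3210.57, 4.78, 5.12, 34.99),
  sd_neg   = c(5.39, 0.07, 18.58, 6.56, 13.59, 9.76, 4.23, 0.81, 1.74,
               4.42, 1.26, 454.58, 0.38, 1.07, 2.55),
  stringsAsFactors = FALSE
)

# Cohort-level category frequencies (all attended, n = 394).
.cohort_categories <- list(
  ethnicity = c(WhiteEuropean = 0.7690, SouthAsian = 0.1168, Other = 0.1142),
  parity = c("1" = 0.4898, ">=2" = 0.5102),
  smoking = c(never = 0.5094, ex = 0.3941, current = 0.0965),
  delivery_mode = c(spontaneous = 0.5038, instrumental = 0.0818,
                    caesarean = 0.4143),
  married = 1 - 0.0574,
  employed = 1 - 0.0256,
  male_baby = 0.4680,
  breastfeeding = 0.5831
)

#' Default class-conditional moments used by the generator
#'
#' One row per feature with the overall and class-conditional mean/SD
#' (positive = postpartum prediabetes, negative = postpartum NGT) that the
#' synthetic-cohort generator emulates.
#'
#' @return data.frame with columns feature, mean_all, sd_all, mean_pos,
#'   sd_pos, mean_neg, sd_neg.
#' @export
default_class_moments <- function() {
  m <- .cohort_moments
  m$feature[m$feature == "weight_implied"] <- "weight"
  m
}

#' Specification for a synthetic GDM cohort
#'
#' Defines the statistical structure of a generated cohort. Two generative
#' modes are supported. In `latent_logistic` mode (the default), antenatal
#' fasting glucose and HbA1c are drawn from the overall cohort distribution
#' (correlation `rho`) and the prediabetes outcome follows
#' `Bernoulli(plogis(b0 + b1 * a_fg + b2 * a_hba1c))`; when `prevalence` is
#' non-NULL the intercept is calibrated by root-finding so the expected
#' prevalence matches it (slopes untouched). In `class_conditional` mode the
#' outcome is drawn first at `prevalence` and features come from the
#' class-specific Gaussians. Gaussian draws are truncated at physiologic
#' floors (glucose > 2 mmol/L, HbA1c > 15 mmol/mol).
#'
#' @param n cohort size (>= 2).
#' @param prevalence target prediabetes prevalence, in (0,1), or NULL (in
#'   latent-logistic mode) to use `b0` uncalibrated.
#' @param outcome_model `"latent_logistic"` or `"class_conditional"`.
#' @param b0,b intercept and named coefficients (per mmol/L of `a_fg`, per
#'   mmol/mol of `a_hba1c`) of the latent outcome model.
#' @param rho correlation between `a_fg` and `a_hba1c`.
#' @param class_moments data.frame as [default_class_moments()]; SDs must be
#'   positive.
#' @param missing_rate MCAR missingness probability per antenatal cell,
#'   in [0,1).
#' @param seed integer seed; every draw is deterministic given it.
#' @return object of class `generator_spec`.
#' @export
generator_spec <- function(n = 394, prevalence = 0.2335,
                           outcome_model = c("latent_logistic",
                                             "class_conditional"),
                           b0 = -8.36, b = c(a_fg = 0.58, a_hba1c = 0.10),
                           rho = 0.3,
                           class_moments = default_class_moments(),
                           missing_rate = 0, seed = 1) {
  outcome_model <- match.arg(outcome_model)
  if (!is.numeric(n) || n < 2) stop("n must be >= 2")
  if (!is.null(prevalence) && (prevalence <= 0 || prevalence >= 1)) {
    stop("prevalence must lie in (0, 1)")
  }
  if (is.null(prevalence) && outcome_model == "class_conditional") {
    stop("class_conditional mode requires a prevalence")
  }
  if (missing_rate < 0 || missing_rate >= 1) stop("missing_rate must lie in [0, 1)")
  if (any(class_moments$sd_all <= 0) || any(class_moments$sd_pos <= 0) ||
      any(class_moments$sd_neg <= 0)) {
    stop("all class SDs must be positive")
  }
  if (abs(rho) >= 1) stop("rho must lie in (-1, 1)")
  if (!setequal(names(b), c("a_fg", "a_hba1c"))) {
    stop("latent model coefficients must be named a_fg and a_hba1c")
  }
  structure(list(n = as.integer(n), prevalence = prevalence,
                 outcome_model = outcome_model, b0 = b0, b = b, rho = rho,
                 class_moments = class_moments,
                 missing_rate = missing_rate, seed = as.integer(seed)),
            class = "generator_spec")
}

# Truncated-normal draw by redraw; floors are far in the tail for every
# cohort feature, so a handful of redraws suffices.
.rnorm_floor <- function(n, mean, sd, floor = -Inf) {
  x <- stats::rnorm(n, mean, sd)
  for (i in 1:50) {
    bad <- x <= floor
    if (!any(bad)) break
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
  }
  x[x <= floor] <- floor + sd * 1e-3
  x
}

.feature_floor <- function(feature) {
  switch(feature,
         a_fg = 2, a_pg = 2, p_fg = 2, p_pg = 2,
         a_hba1c = 15, p_hba1c = 15,
         height = 1.2, bmi = 12, age = 14, sbp = 60, dbp = 35,
         ga_ogtt = 16, ga_birth = 24, birth_weight = 500,
         -Inf)
}

.moment_row <- function(moments, feature) {
  moments[moments$feature == feature, , drop = FALSE]
}

# Bivariate normal (a_fg, a_hba1c) with given per-class moments.
.draw_glycaemia <- function(n, m_fg, s_fg, m_h, s_h, rho) {
  z1 <- stats::rnorm(n)
  z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(n)
  fg <- m_fg + s_fg * z1
  hb <- m_h + s_h * z2
  fg[fg <= 2] <- 2 + s_fg * 1e-3
  hb[hb <= 15] <- 15 + s_h * 1e-3
  cbind(a_fg = fg, a_hba1c = hb)
}

# Postpartum biochemistry consistent with the assigned outcome under NICE
# labelling: positives satisfy the prediabetes rule (and not the diabetes
# rule), negatives fall below every threshold. Rejection sampling from the
# class-conditional Gaussians with a deterministic fallback.
.draw_postpartum <- function(outcome, moments) {
  n <- length(outcome)
  out <- matrix(NA_real_, n, 3, dimnames = list(NULL, c("p_fg", "p_pg", "p_hba1c")))
  ms <- lapply(c("p_fg", "p_pg", "p_hba1c"), function(f) .moment_row(moments, f))
  names(ms) <- c("p_fg", "p_pg", "p_hba1c")
  pre_lo <- c(5.6, 7.8, 40); t2_lo <- c(7.0, 11.1, 48)
  for (i in seq_len(n)) {
    pos <- outcome[i] == 1L
    mu <- sapply(ms, function(m) if (pos) m$mean_pos else m$mean_neg)
    sg <- sapply(ms, function(m) if (pos) m$sd_pos else m$sd_neg)
    ok <- FALSE
    for (try in 1:100) {
      x <- stats::rnorm(3, mu, sg)
      x <- pmax(x, c(2.001, 2.001, 15.001))
      if (pos) {
        ok <- any(x >= pre_lo) && all(x < t2_lo)
      } else {
        ok <- all(x < pre_lo)
      }
      if (ok) break
    }
    if (!ok) {
      x <- if (pos) c(5.9, 6.5, 41) else c(4.7, 5.0, 34)
    }
    out[i, ] <- x
  }
  out
}

#' Generate a synthetic GDM cohort
#'
#' Draws a cohort with the structure described by a [generator_spec()]:
#' antenatal and delivery covariates from the class (or overall) Gaussians
#' and category frequencies, a prediabetes outcome from the latent logistic
#' model or by class-conditional sampling, and postpartum biochemistry
#' consistent with the assigned outcome, so that [label_cohort()] under NICE
#' criteria recovers it. Weight is derived as `bmi * height^2`, keeping the
#' BMI consistency invariant exact. Deterministic given `spec$seed`.
#'
#' @param spec a [generator_spec()].
#' @return A labelled [cohort_table()] (columns `status`,
#'   `triggering_measures` included).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  set.seed(spec$seed)
  n <- spec$n
  mom <- spec$class_moments

  if (spec$outcome_model == "latent_logistic") {
    fgm <- .moment_row(mom, "a_fg"); hbm <- .moment_row(mom, "a_hba1c")
    gly <- .draw_glycaemia(n, fgm$mean_all, fgm$sd_all,
                           hbm$mean_all, hbm$sd_all, spec$rho)
    eta <- spec$b0 + spec$b[["a_fg"]] * gly[, "a_fg"] +
      spec$b[["a_hba1c"]] * gly[, "a_hba1c"]
    if (!is.null(spec$prevalence)) {
      # calibrate the intercept so the mean risk over the drawn covariates
      # equals the requested prevalence; slopes untouched
      delta <- stats::uniroot(
        function(d) mean(stats::plogis(eta + d)) - spec$prevalence,
        c(-20, 20))$root
      eta <- eta + delta
    }
    outcome <- stats::rbinom(n, 1L, stats::plogis(eta))
  } else {
    outcome <- stats::rbinom(n, 1L, spec$prevalence)
    fgm <- .moment_row(mom, "a_fg"); hbm <- .moment_row(mom, "a_hba1c")
    gly <- matrix(NA_real_, n, 2, dimnames = list(NULL, c("a_fg", "a_hba1c")))
    for (cls in c(0L, 1L)) {
      idx <- which(outcome == cls)
      if (length(idx) == 0) next
      if (cls == 1L) {
        gly[idx, ] <- .draw_glycaemia(length(idx), fgm$mean_pos, fgm$sd_pos,
                                      hbm$mean_pos, hbm$sd_pos, spec$rho)
      } else {
        gly[idx, ] <- .draw_glycaemia(length(idx), fgm$mean_neg, fgm$sd_neg,
                                      hbm$mean_neg, hbm$sd_neg, spec$rho)
      }
    }
  }

  draw_feature <- function(feature) {
    m <- .moment_row(mom, feature)
    x <- numeric(n)
    for (cls in c(0L, 1L)) {
      idx <- which(outcome == cls)
      if (length(idx) == 0) next
      mu <- if (cls == 1L) m$mean_pos else m$mean_neg
      sg <- if (cls == 1L) m$sd_pos else m$sd_neg
      x[idx] <- .rnorm_floor(length(idx), mu, sg, .feature_floor(feature))
    }
    x
  }

  df <- data.frame(id = sprintf("W%05d", seq_len(n)))
  df$age <- draw_feature("age")
  df$height <- draw_feature("height")
  df$bmi <- draw_feature("bmi")
  df$weight <- df$bmi * df$height^2
  df$sbp <- draw_feature("sbp")
  df$dbp <- draw_feature("dbp")
  cat_draw <- function(p) sample(names(p), n, replace = TRUE, prob = p)
  df$ethnicity <- cat_draw(.cohort_categories$ethnicity)
  df$parity <- cat_draw(.cohort_categories$parity)
  df$gravida <- ifelse(df$parity == "1", 1, 2) + stats::rpois(n, 0.4)
  df$smoking <- cat_draw(.cohort_categories$smoking)
  df$married <- stats::runif(n) < .cohort_categories$married
  df$employed <- stats::runif(n) < .cohort_categories$employed
  df$ga_ogtt <- draw_feature("ga_ogtt")
  df$a_fg <- gly[, "a_fg"]
  df$a_pg <- draw_feature("a_pg")
  df$a_hba1c <- gly[, "a_hba1c"]
  df$ga_birth <- draw_feature("ga_birth")
  df$delivery_mode <- cat_draw(.cohort_categories$delivery_mode)
  df$birth_weight <- draw_feature("birth_weight")
  df$male_baby <- stats::runif(n) < .cohort_categories$male_baby
  df$breastfeeding <- stats::runif(n) < .cohort_categories$breastfeeding

  pp <- .draw_postpartum(outcome, mom)
  df$p_fg <- pp[, "p_fg"]; df$p_pg <- pp[, "p_pg"]; df$p_hba1c <- pp[, "p_hba1c"]

  tab <- label_cohort(cohort_table(df), "NICE")
  if (spec$missing_rate > 0) {
    tab <- inject_missingness(tab, spec$missing_rate, seed = spec$seed + 1L)
  }
  tab
}

#' Inject MCAR missingness into antenatal features
#'
#' Masks each antenatal feature cell independently with probability `rate`
#' (missing completely at random). Outcome-defining postpartum fields and
#' identifiers are never masked. Deterministic given `seed`.
#'
#' @param table a [cohort_table()].
#' @param rate masking probability, in [0, 1).
#' @param seed integer seed.
#' @return The table with masked cells set to NA.
#' @export
inject_missingness <- function(table, rate, seed = 1) {
  if (rate < 0 || rate >= 1) stop("rate must lie in [0, 1)")
  if (rate == 0) return(table)
  set.seed(seed)
  cols <- intersect(antenatal_features(), names(table))
  n <- nrow(table)
  for (col in cols) {
    mask <- stats::runif(n) < rate
    table[[col]][mask] <- NA
  }
  table
}
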