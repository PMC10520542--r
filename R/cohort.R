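# Canonical column set for a cohort table. Antenatal covariates are measured
# at or around the diagnostic OGTT; postpartum measures (p_*) are the
# outcome-defining biochemistry at 6-13 weeks after delivery and may be absent.
.cohort_numeric <- c(
  "age", "height", "weight", "bmi", "sbp", "dbp", "gravida", "ga_ogtt",
  "a_fg", "a_pg", "a_hba1c", "ga_birth", "birth_weight",
  "p_fg", "p_pg", "p_hba1c"
)

.cohort_factors <- list(
  ethnicity = c("WhiteEuropean", "SouthAsian", "Other"),
  parity = c("1", ">=2"),
  smoking = c("never", "ex", "current"),
  delivery_mode = c("spontaneous", "instrumental", "caesarean")
)

.cohort_flags <- c("married", "employed", "male_baby", "breastfeeding")

#' Canonical cohort column names
#'
#' @return Character vector of all recognised cohort columns, in canonical
#'   order (`id` first, then antenatal, delivery and postpartum fields).
#' @export
cohort_columns <- function() {
  c("id", "age", "height", "weight", "bmi", "sbp", "dbp", "ethnicity",
    "parity", "gravida", "smoking", "married", "employed", "ga_ogtt",
    "a_fg", "a_pg", "a_hba1c", "ga_birth", "delivery_mode", "birth_weight",
    "male_baby", "breastfeeding", "p_fg", "p_pg", "p_hba1c")
}

#' Antenatal feature names
#'
#' The covariates available before delivery, i.e. the candidate predictors
#' for antenatal risk prediction. Missingness injection and the modelling
#' default feature set operate on these (plus delivery variables where
#' requested).
#'
#' @param include_delivery also include delivery/neonatal variables.
#' @return Character vector of column names.
#' @export
antenatal_features <- function(include_delivery = FALSE) {
  ante <- c("age", "height", "weight", "bmi", "sbp", "dbp", "ethnicity",
            "parity", "gravida", "smoking", "married", "employed",
            "ga_ogtt", "a_fg", "a_pg", "a_hba1c")
  if (include_delivery) {
    ante <- c(ante, "ga_birth", "delivery_mode", "birth_weight",
              "male_baby", "breastfeeding")
  }
  ante
}

#' Construct a cohort table
#'
#' Validates a data frame of per-woman records against the canonical schema
#' and attaches the `cohort_table` class. Glucose values must be strictly
#' positive when present; where height, weight and BMI are all present, BMI
#' must agree with weight/height^2 within 5% (audit-grade tolerance).
#'
#' @param df data frame with (a subset of) [cohort_columns()].
#' @return The validated data frame with class `cohort_table`.
#' @export
cohort_table <- function(df) {
  stopifnot(is.data.frame(df))
  if (!"id" %in% names(df)) df$id <- sprintf("W%05d", seq_len(nrow(df)))
  df$id <- as.character(df$id)
  for (col in intersect(.cohort_numeric, names(df))) {
    df[[col]] <- as.numeric(df[[col]])
  }
  for (col in intersect(names(.cohort_factors), names(df))) {
    df[[col]] <- factor(as.character(df[[col]]), levels = .cohort_factors[[col]])
  }
  for (col in intersect(.cohort_flags, names(df))) {
    df[[col]] <- as.logical(df[[col]])
  }
  glu <- intersect(c("a_fg", "a_pg", "p_fg", "p_pg"), names(df))
  for (col in glu) {
    bad <- !is.na(df[[col]]) & (!is.finite(df[[col]]) | df[[col]] <= 0)
    if (any(bad)) {
      stop(sprintf("column '%s' has %d non-positive or non-finite glucose values",
                   col, sum(bad)))
    }
  }
  if (all(c("height", "weight", "bmi") %in% names(df))) {
    ok <- complete.cases(df[, c("height", "weight", "bmi")])
    if (any(ok)) {
      implied <- df$weight[ok] / df$height[ok]^2
      rel <- abs(df$bmi[ok] - implied) / implied
      if (any(rel > 0.05)) {
        stop(sprintf("%d rows have BMI inconsistent with weight/height^2 by more than 5%%",
                     sum(rel > 0.05)))
      }
    }
  }
  class(df) <- c("cohort_table", "data.frame")
  df
}

#' Read a cohort CSV
#'
#' Reads an RFC-4180 style, UTF-8, "."-decimal CSV with a header row into a
#' [cohort_table()]. Arbitrary headers are adapted through `dialect`, a named
#' character vector mapping canonical names to the file's column names.
#' Unparseable numeric cells become missing values with a warning giving the
#' per-column count. `a_fg` and `a_hba1c` are mandatory.
#'
#' @param path path to a delimited text file with a header row.
#' @param dialect named character vector, `canonical = "file_column"`. Columns
#'   not mentioned are matched by canonical name.
#' @param missing_markers cell values treated as missing.
#' @return A [cohort_table()] with one record per data row, order preserved.
#' @export
read_cohort <- function(path, dialect = NULL,
                        missing_markers = c("", "NA", "NaN")) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                         fileEncoding = "UTF-8")
  if (ncol(raw) == 0) stop("empty file: ", path)
  if (!is.null(dialect)) {
    for (canon in names(dialect)) {
      src <- dialect[[canon]]
      if (src %in% names(raw)) names(raw)[names(raw) == src] <- canon
    }
  }
  keep <- intersect(cohort_columns(), names(raw))
  mandatory <- c("a_fg", "a_hba1c")
  absent <- setdiff(mandatory, keep)
  if (length(absent) > 0) {
    stop("mandatory column(s) missing: ", paste(absent, collapse = ", "))
  }
  raw <- raw[, keep, drop = FALSE]
  for (col in names(raw)) {
    raw[[col]][raw[[col]] %in% missing_markers] <- NA
  }
  n_bad <- integer(0)
  for (col in intersect(.cohort_numeric, names(raw))) {
    parsed <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- is.na(parsed) & !is.na(raw[[col]])
    if (any(bad)) n_bad[col] <- sum(bad)
    raw[[col]] <- parsed
  }
  if (length(n_bad) > 0) {
    warning("unparseable numeric cells set to missing: ",
            paste(sprintf("%s (%d)", names(n_bad), n_bad), collapse = ", "))
  }
  cohort_table(raw)
}

#' Write a cohort CSV
#'
#' Inverse of [read_cohort()]: canonical headers, empty cells for missing
#' values.
#'
#' @param table a [cohort_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(table, path) {
  out <- as.data.frame(table)[, intersect(cohort_columns(), names(table)),
                              drop = FALSE]
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

# Glycaemic thresholds by criteria set. Prediabetes lower bounds; the
# incident-diabetes thresholds are shared by all three rule-sets. WHO has no
# HbA1c criterion for prediabetes; ADA's HbA1c bound is 39 mmol/mol (5.7%).
.prediabetes_thresholds <- list(
  NICE = c(fasting = 5.6, postprandial = 7.8, hba1c = 40),
  WHO  = c(fasting = 6.1, postprandial = 7.8, hba1c = Inf),
  ADA  = c(fasting = 5.6, postprandial = 7.8, hba1c = 39)
)
.t2dm_thresholds <- c(fasting = 7.0, postprandial = 11.1, hba1c = 48)

#' Label postpartum glucose-tolerance outcome
#'
#' Applies the rule-in thresholds of the chosen criteria set to the
#' postpartum measures of one record. All comparisons are inclusive (>=).
#' Incident diabetes takes precedence over prediabetes; a record with no
#' postpartum measure is `unlabelled`.
#'
#' @param record a list / one-row data frame with (possibly missing)
#'   `p_fg` (mmol/L), `p_pg` (mmol/L), `p_hba1c` (mmol/mol).
#' @param criteria one of `"NICE"` (default), `"WHO"`, `"ADA"`.
#' @return list with `status` (factor in NGT < prediabetes < T2DM, or
#'   `unlabelled`) and `triggering_measures` (character subset of
#'   fasting/postprandial/hba1c that fired).
#' @export
label_outcome <- function(record, criteria = c("NICE", "WHO", "ADA")) {
  criteria <- match.arg(criteria)
  vals <- c(fasting = .scalar_or_na(record$p_fg),
            postprandial = .scalar_or_na(record$p_pg),
            hba1c = .scalar_or_na(record$p_hba1c))
  lv <- c("NGT", "prediabetes", "T2DM", "unlabelled")
  if (all(is.na(vals))) {
    return(list(status = factor("unlabelled", levels = lv),
                triggering_measures = character(0)))
  }
  t2 <- !is.na(vals) & vals >= .t2dm_thresholds
  if (any(t2)) {
    return(list(status = factor("T2DM", levels = lv),
                triggering_measures = names(vals)[t2]))
  }
  pre <- !is.na(vals) & vals >= .prediabetes_thresholds[[criteria]]
  if (any(pre)) {
    return(list(status = factor("prediabetes", levels = lv),
                triggering_measures = names(vals)[pre]))
  }
  list(status = factor("NGT", levels = lv), triggering_measures = character(0))
}

.scalar_or_na <- function(x) {
  if (is.null(x) || length(x) == 0 || is.na(x[1])) NA_real_ else as.numeric(x[1])
}

#' Label every record of a cohort table
#'
#' @param table a [cohort_table()].
#' @param criteria criteria set, see [label_outcome()].
#' @return `table` with columns `status` (factor) and `triggering_measures`
#'   ("+"-joined character) appended.
#' @export
label_cohort <- function(table, criteria = c("NICE", "WHO", "ADA")) {
  criteria <- match.arg(criteria)
  labs <- lapply(seq_len(nrow(table)), function(i) {
    label_outcome(as.list(table[i, c("p_fg", "p_pg", "p_hba1c")[
      c("p_fg", "p_pg", "p_hba1c") %in% names(table)]]), criteria)
  })
  table$status <- factor(vapply(labs, function(l) as.character(l$status), ""),
                         levels = c("NGT", "prediabetes", "T2DM", "unlabelled"))
  table$triggering_measures <- vapply(
    labs, function(l) paste(l$triggering_measures, collapse = "+"), "")
  table
}

#' Binary prediabetes outcome
#'
#' The modelling outcome: 1 for prediabetes or incident diabetes, 0 for
#' normal glucose tolerance, NA where no postpartum measure was available.
#'
#' @param table a labelled cohort table (see [label_cohort()]).
#' @return integer vector of 0/1/NA.
#' @export
outcome_binary <- function(table) {
  if (is.null(table$status)) stop("table has no 'status' column; run label_cohort() first")
  ifelse(table$status == "unlabelled", NA_integer_,
         as.integer(table$status %in% c("prediabetes", "T2DM")))
}
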