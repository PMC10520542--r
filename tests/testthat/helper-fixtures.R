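# Shared fixtures: tiny in-code cohorts and prediction sets.

toy_preds <- function(prob, label) {
  aggregated_predictions(data.frame(id = as.character(seq_along(prob)),
                                    fold = seq_along(prob),
                                    prob = prob, label = label))
}

# Minimal 5-row cohort covering categories, flags and missing cells.
tiny_cohort <- function() {
  cohort_table(data.frame(
    id = sprintf("W%02d", 1:5),
    age = c(28, 34, NA, 41, 30),
    height = c(1.60, 1.72, 1.65, 1.58, 1.70),
    weight = c(64.0, 88.8, 70.1, 82.4, 95.3),
    bmi = c(64.0 / 1.60^2, 88.8 / 1.72^2, 70.1 / 1.65^2,
            82.4 / 1.58^2, 95.3 / 1.70^2),
    sbp = c(110, 125, 118, NA, 121),
    dbp = c(70, 82, 76, 68, 74),
    ethnicity = c("WhiteEuropean", "SouthAsian", "Other",
                  "WhiteEuropean", "WhiteEuropean"),
    parity = c("1", ">=2", "1", ">=2", "1"),
    gravida = c(1, 3, 1, 2, 1),
    smoking = c("never", "ex", "current", "never", "never"),
    married = c(TRUE, TRUE, FALSE, TRUE, TRUE),
    employed = c(TRUE, TRUE, TRUE, FALSE, TRUE),
    ga_ogtt = c(26.5, 28.0, 31.2, 24.9, 27.4),
    a_fg = c(4.4, 5.6, 4.9, 6.1, 4.7),
    a_pg = c(7.9, 9.4, NA, 10.2, 8.1),
    a_hba1c = c(33, 39, 35, 42, 34),
    ga_birth = c(38.2, 37.1, 39.0, 36.8, 38.5),
    delivery_mode = c("spontaneous", "caesarean", "spontaneous",
                      "instrumental", "caesarean"),
    birth_weight = c(3100, 3600, 3300, 2950, 3450),
    male_baby = c(TRUE, FALSE, TRUE, TRUE, FALSE),
    breastfeeding = c(TRUE, TRUE, FALSE, TRUE, TRUE),
    p_fg = c(4.8, 5.9, 4.6, 7.2, NA),
    p_pg = c(5.0, 8.1, 5.5, 11.5, NA),
    p_hba1c = c(35, 41, 33, 49, NA),
    stringsAsFactors = FALSE))
}

# O(n^2) pairwise concordance oracle for the AUC (ties count 1/2).
auc_oracle <- function(prob, label) {
  pos <- prob[label == 1]; neg <- prob[label == 0]
  d <- outer(pos, neg, "-")
  (sum(d > 0) + 0.5 * sum(d == 0)) / (length(pos) * length(neg))
}

# Mutual information of the 2x2 (disease, test) joint from (x, g1, g2).
mutual_information_oracle <- function(x, g1, g2) {
  p <- c(x * g1, x * (1 - g1), (1 - x) * (1 - g2), (1 - x) * g2)
  pd <- c(x, x, 1 - x, 1 - x)
  pt <- c(x * g1 + (1 - x) * (1 - g2), 1 - (x * g1 + (1 - x) * (1 - g2)),
          x * g1 + (1 - x) * (1 - g2), 1 - (x * g1 + (1 - x) * (1 - g2)))
  nz <- p > 0
  sum(p[nz] * log(p[nz] / (pd[nz] * pt[nz])))
}
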