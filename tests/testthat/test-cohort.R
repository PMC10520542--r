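test_that("outcome labelling follows the threshold rules", {
  # prediabetes fires on fasting alone at exactly the NICE bound
  l <- label_outcome(list(p_fg = 5.6, p_pg = 7.0, p_hba1c = 38), "NICE")
  expect_equal(as.character(l$status), "prediabetes")
  expect_equal(l$triggering_measures, "fasting")

  # incident diabetes from a single fasting measure, others absent
  l <- label_outcome(list(p_fg = 7.0), "NICE")
  expect_equal(as.character(l$status), "T2DM")
  expect_equal(l$triggering_measures, "fasting")

  # no postpartum information at all
  l <- label_outcome(list(), "NICE")
  expect_equal(as.character(l$status), "unlabelled")
  expect_length(l$triggering_measures, 0)

  # all below thresholds
  l <- label_outcome(list(p_fg = 4.8, p_pg = 5.0, p_hba1c = 35), "NICE")
  expect_equal(as.character(l$status), "NGT")
  expect_length(l$triggering_measures, 0)

  # diabetes takes precedence when both rule-sets fire
  l <- label_outcome(list(p_fg = 7.4, p_pg = 8.5), "NICE")
  expect_equal(as.character(l$status), "T2DM")

  # WHO has no HbA1c prediabetes criterion and a higher fasting bound
  expect_equal(as.character(label_outcome(list(p_fg = 5.8, p_hba1c = 45), "WHO")$status),
               "NGT")
  expect_equal(as.character(label_outcome(list(p_fg = 6.1), "WHO")$status),
               "prediabetes")
  # ADA's HbA1c bound is 39 mmol/mol
  expect_equal(as.character(label_outcome(list(p_hba1c = 39), "ADA")$status),
               "prediabetes")
  expect_equal(as.character(label_outcome(list(p_hba1c = 39), "NICE")$status),
               "NGT")
})

test_that("labelling is monotone in every postpartum measure", {
  sev <- c(unlabelled = 0, NGT = 1, prediabetes = 2, T2DM = 3)
  set.seed(1)
  for (i in 1:200) {
    rec <- list(p_fg = runif(1, 3, 9), p_pg = runif(1, 3, 13),
                p_hba1c = runif(1, 25, 55))
    before <- sev[[as.character(label_outcome(rec, "NICE")$status)]]
    bump <- sample(names(rec), 1)
    rec[[bump]] <- rec[[bump]] + runif(1, 0, 3)
    after <- sev[[as.character(label_outcome(rec, "NICE")$status)]]
    expect_gte(after, before)
  }
})

test_that("triggering measures are empty exactly for NGT among labelled records", {
  tab <- label_cohort(tiny_cohort(), "NICE")
  labelled <- tab$status != "unlabelled"
  expect_equal(tab$triggering_measures[labelled] == "",
               tab$status[labelled] == "NGT")
})

test_that("a table with one measure at its NICE threshold is all prediabetes", {
  df <- data.frame(a_fg = rep(5, 3), a_hba1c = rep(35, 3),
                   p_fg = c(5.6, NA, NA), p_pg = c(NA, 7.8, NA),
                   p_hba1c = c(NA, NA, 40))
  tab <- label_cohort(cohort_table(df), "NICE")
  expect_true(all(tab$status == "prediabetes"))
})

test_that("cohort CSV round-trips field by field", {
  tab <- tiny_cohort()
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(tab, path)
  back <- read_cohort(path)
  for (col in intersect(cohort_columns(), names(tab))) {
    expect_equal(back[[col]], tab[[col]], info = col)
  }
})

test_that("reader handles empty tables, missing markers and bad cells", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines("id,a_fg,a_pg,a_hba1c", path)
  empty <- read_cohort(path)
  expect_s3_class(empty, "cohort_table")
  expect_equal(nrow(empty), 0)

  writeLines(c("id,a_fg,a_pg,a_hba1c", "W1,4.9,NA,35", "W2,5.2,not-a-number,38"),
             path)
  expect_warning(tab <- read_cohort(path), "unparseable")
  expect_true(is.na(tab$a_pg[1]))
  expect_true(is.na(tab$a_pg[2]))
  expect_equal(tab$a_fg, c(4.9, 5.2))

  writeLines(c("id,a_pg", "W1,8.0"), path)
  expect_error(read_cohort(path), "a_fg")
})

test_that("dialect mapping adapts arbitrary headers", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("pid,fasting,hba1c", "W1,5.1,36"), path)
  tab <- read_cohort(path, dialect = c(id = "pid", a_fg = "fasting",
                                       a_hba1c = "hba1c"))
  expect_equal(tab$a_fg, 5.1)
  expect_equal(tab$a_hba1c, 36)
})

test_that("cohort validation rejects impossible values", {
  expect_error(cohort_table(data.frame(a_fg = -1, a_hba1c = 35)),
               "non-positive")
  expect_error(cohort_table(data.frame(height = 1.6, weight = 60,
                                       bmi = 40, a_fg = 5, a_hba1c = 35)),
               "BMI")
})
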