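test_that("K-L divergences match hand calculations and symmetries", {
  # uninformative test: the two response distributions coincide
  expect_equal(kl_in(0.7, 0.3), 0)
  expect_equal(kl_out(0.7, 0.3), 0)
  # 0.8 * ln 9
  expect_equal(round(kl_in(0.9, 0.9), 4), 1.7578)
  # defining-formula symmetry
  g <- expand.grid(g1 = seq(0.1, 0.9, 0.2), g2 = seq(0.1, 0.9, 0.2))
  expect_equal(kl_in(g$g1, g$g2), kl_out(g$g2, g$g1))
  expect_true(all(kl_in(g$g1, g$g2) >= 0))
  expect_error(kl_in(1.2, 0.5), "must lie")
})

test_that("odds multipliers and distinguishability transform divergences", {
  expect_equal(pin_pout(0), 1)
  expect_equal(info_distinguishability(0), 0)
  expect_equal(round(pin_pout(0.30), 2), 1.35)
  expect_equal(round(info_distinguishability(0.2965), 4), 0.2566)
  expect_error(pin_pout(-0.1), ">= 0")
})

test_that("divergences are jointly zero exactly on the uninformative line", {
  g <- expand.grid(g1 = seq(0.05, 0.95, 0.05), g2 = seq(0.05, 0.95, 0.05))
  tot <- kl_in(g$g1, g$g2) + kl_out(g$g1, g$g2)
  on_line <- abs(g$g1 + g$g2 - 1) < 1e-12
  expect_true(all(tot[on_line] < 1e-12))
  expect_true(all(tot[!on_line] > 0))
})

test_that("threshold metric rows are internally consistent", {
  set.seed(31)
  preds <- toy_preds(round(runif(80), 2), rbinom(80, 1, 0.3))
  for (cc in c(0.1, 0.25, 0.5, 0.75)) {
    row <- threshold_metrics(preds, cc)
    expect_equal(row$youden, row$g1 + row$g2 - 1, tolerance = 1e-12)
    expect_equal(row$tkl, row$kl_in + row$kl_out, tolerance = 1e-12)
    expect_equal(row$p_in, exp(row$kl_in), tolerance = 1e-12)
    expect_equal(row$id_in, 1 - exp(-row$kl_in), tolerance = 1e-12)
    expect_equal(row$p_out, exp(row$kl_out), tolerance = 1e-12)
    expect_equal(row$id_out, 1 - exp(-row$kl_out), tolerance = 1e-12)
    # Bayes' identity at the empirical prevalence
    pi <- mean(preds$label)
    expect_equal(row$ppv,
                 pi * row$g1 / (pi * row$g1 + (1 - pi) * (1 - row$g2)),
                 tolerance = 1e-12)
    expect_equal(row$npv,
                 (1 - pi) * row$g2 / ((1 - pi) * row$g2 + pi * (1 - row$g1)),
                 tolerance = 1e-12)
    expect_equal(row$f1, 2 * row$ppv * row$g1 / (row$ppv + row$g1),
                 tolerance = 1e-12)
  }
})

test_that("metric rows reproduce the published operating characteristics", {
  # at the combined rule-in/rule-out cut-point: sensitivity 0.58,
  # specificity 0.76 gives Youden J = 0.34
  dm <- divergence_metrics(0.58, 0.76)
  expect_equal(round(dm$youden, 2), 0.34)
  # with PPV 0.4274 the F1 score is 0.49
  expect_equal(round(2 * 0.4274 * 0.58 / (0.4274 + 0.58), 2), 0.49)
  # perfect separation at an interior cut-point
  perfect <- toy_preds(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  row <- threshold_metrics(perfect, 0.5)
  expect_equal(unlist(row[c("g1", "g2", "ppv", "npv", "accuracy", "youden")]),
               c(g1 = 1, g2 = 1, ppv = 1, npv = 1, accuracy = 1, youden = 1))
})

test_that("cut-point scan is monotone and matches a brute-force oracle", {
  set.seed(32)
  for (i in 1:20) {
    n <- sample(20:50, 1)
    y <- c(1, 0, rbinom(n - 2, 1, 0.35))  # both classes guaranteed
    s <- round(runif(n), 3)
    preds <- toy_preds(s, y)
    scan <- scan_cutpoints(preds)
    # monotone: g1 non-increasing, g2 non-decreasing in c
    expect_true(all(diff(scan$rows$g1) <= 1e-12))
    expect_true(all(diff(scan$rows$g2) >= -1e-12))
    # brute-force oracle over every attainable threshold (the distinct
    # scores), with the same degenerate-row exclusion
    cand <- sort(unique(c(0, s)))
    rows <- do.call(rbind, lapply(cand, function(cc) {
      as.data.frame(threshold_metrics(preds, cc))
    }))
    ok <- if (all(rows$degenerate)) rep(TRUE, nrow(rows)) else !rows$degenerate
    expect_equal(scan$selection$d_in, max(rows$kl_in[ok]), tolerance = 1e-12)
    expect_equal(scan$selection$d_out, max(rows$kl_out[ok]), tolerance = 1e-12)
    expect_equal(scan$selection$tkl_max, max(rows$tkl[ok]), tolerance = 1e-12)
  }
})

test_that("symmetric separation puts the combined cut-point at the midpoint", {
  set.seed(33)
  n <- 2000
  y <- rep(c(1, 0), each = n / 2)
  s <- ifelse(y == 1, runif(n, 0.5, 1), runif(n, 0, 0.5))
  scan <- scan_cutpoints(toy_preds(s, y))
  expect_lt(abs(scan$selection$c_in_out - 0.5), 0.02)
})

test_that("anti-informative scores are flagged", {
  set.seed(34)
  n <- 200
  y <- rep(c(1, 0), each = n / 2)
  s <- ifelse(y == 1, runif(n, 0, 0.45), runif(n, 0.55, 1))  # flipped
  scan <- scan_cutpoints(toy_preds(s, y))
  expect_true(scan$selection$flagged)
  expect_lte(scan$selection$youden_at_in_out, 0)
})

test_that("the ta column counts the percent of scores below the cut-point", {
  preds <- toy_preds(c(0.05, 0.10, 0.20, 0.30, 0.90, 0.95),
                     c(0, 0, 0, 1, 1, 1))
  expect_equal(threshold_metrics(preds, 0.25)$ta, 50)
  expect_equal(threshold_metrics(preds, 0.10)$ta, round(100 / 6))
})

test_that("information graphs decompose expected information exactly", {
  set.seed(35)
  for (i in 1:50) {
    g1 <- runif(1, 0.05, 0.95); g2 <- runif(1, 0.05, 0.95)
    x <- runif(1, 0.02, 0.98)
    ig <- information_graph(g1, g2, x)
    expect_equal(ig$i_expected, ig$pr_t1 * ig$i_plus + (1 - ig$pr_t1) * ig$i_minus,
                 tolerance = 1e-10)
    # expected information is the mutual information of the 2x2 joint
    expect_equal(ig$i_expected, mutual_information_oracle(x, g1, g2),
                 tolerance = 1e-10)
    expect_true(all(c(ig$i_plus, ig$i_minus, ig$i_expected) >= 0))
  }

  # uninformative test: posterior equals prior at every pre-test probability
  ig <- information_graph(0.6, 0.4, seq(0.1, 0.9, 0.1))
  expect_lt(max(abs(ig$i_plus)), 1e-12)
  expect_lt(max(abs(ig$i_minus)), 1e-12)
  expect_lt(max(abs(ig$i_expected)), 1e-12)

  # for a rule-in-shaped test (high specificity), a positive result is most
  # informative at low pre-test probability, where i_minus vanishes
  ig <- information_graph(0.36, 0.92, c(0.001, 0.01, 0.05))
  expect_true(all(diff(ig$i_minus) >= 0))
  expect_true(all(ig$i_plus > ig$i_minus))
})

test_that("the Bregman tangent construction equals the total divergence", {
  g <- expand.grid(g1 = seq(0.045, 0.955, length.out = 20),
                   g2 = seq(0.045, 0.955, length.out = 20))
  breg <- bregman_total_kl(g$g1, g$g2)
  expect_equal(breg, kl_in(g$g1, g$g2) + kl_out(g$g1, g$g2),
               tolerance = 1e-10)
  expect_true(all(breg >= -1e-12))
  expect_equal(bregman_total_kl(0.7, 0.3), 0)
})
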