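test_that("2x2 odds ratios match published contingency examples", {
  est <- oddsRatioFromCounts(56, 70, 94, 231)
  expect_equal(est$odds_ratio, 1.97, tolerance = 0.005)
  expect_lt(est$p_value, 0.01)
  expect_equal(oddsRatioFromCounts(29, 12, 200, 210)$odds_ratio, 2.54,
               tolerance = 0.005)
  # a balanced table carries no association
  flat <- oddsRatioFromCounts(7, 7, 7, 7)
  expect_equal(flat$odds_ratio, 1)
  expect_equal(flat$p_value, 1)
})

test_that("odds-ratio algebra: transposition inverts, zero cells undefine", {
  est <- oddsRatioFromCounts(12, 5, 7, 21)
  tr <- oddsRatioFromCounts(7, 21, 12, 5)  # rows swapped
  expect_equal(est$odds_ratio, 1 / tr$odds_ratio)
  expect_equal(est$p_value, tr$p_value)
  zero <- oddsRatioFromCounts(0, 10, 5, 20)
  expect_true(is.na(zero$odds_ratio))
  expect_false(is.na(zero$p_value))
  haldane <- oddsRatioFromCounts(0, 10, 5, 20, haldane = TRUE)
  expect_false(is.na(haldane$odds_ratio))
  expect_error(oddsRatioFromCounts(-1, 2, 3, 4), "non-negative")
})

test_that("Woolf interval brackets the estimate and narrows as counts scale", {
  est <- oddsRatioFromCounts(20, 30, 15, 45)
  expect_lt(est$ci_low, est$odds_ratio)
  expect_gt(est$ci_high, est$odds_ratio)
  est4 <- oddsRatioFromCounts(80, 120, 60, 180)
  expect_equal(log(est4$ci_high / est4$ci_low),
               log(est$ci_high / est$ci_low) / 2, tolerance = 1e-12)
})

test_that("frequency-based odds ratios reproduce published per-locus values", {
  expect_equal(oddsRatioFromFreqs(0.1542, 0.0734)$odds_ratio, 2.30,
               tolerance = 0.005)
  expect_equal(oddsRatioFromFreqs(0.1429, 0.0538)$odds_ratio, 2.93,
               tolerance = 0.005)
  expect_equal(oddsRatioFromFreqs(0.3, 0.3)$odds_ratio, 1)
  expect_true(is.na(oddsRatioFromFreqs(0, 0.2)$odds_ratio))
  expect_true(is.na(oddsRatioFromFreqs(0.2, 1)$odds_ratio))
  expect_error(oddsRatioFromFreqs(1.2, 0.5), "\\[0, 1\\]")
})

test_that("Fisher's exact equals exhaustive enumeration for small tables", {
  set.seed(42)
  for (i in 1:40) {
    n <- sample(4:12, 1)
    cells <- as.vector(stats::rmultinom(1, n, prob = runif(4, 0.1, 1)))
    p_pkg <- fisherExact2x2(cells[1], cells[2], cells[3], cells[4])
    p_ora <- fisher_oracle(cells[1], cells[2], cells[3], cells[4])
    expect_equal(p_pkg, p_ora, tolerance = 1e-9)
  }
})

test_that("AUROC equals the all-pairs statistic and is rank-invariant", {
  expect_equal(rocAuc(c(1, 2, 3, 4), c(0, 0, 1, 1))$auc, 1)
  set.seed(7)
  for (i in 1:30) {
    n <- sample(4:12, 1)
    labels <- c(0, 1, rbinom(n - 2, 1, 0.5))  # both classes guaranteed
    scores <- sample(1:6, n, replace = TRUE)  # ties likely
    r <- rocAuc(scores, labels)
    expect_equal(r$auc, auc_oracle(scores, labels), tolerance = 1e-12)
    # invariance under a strictly increasing transform
    expect_equal(rocAuc(exp(scores / 2), labels)$auc, r$auc,
                 tolerance = 1e-12)
    expect_true(all(r$sens >= 0 & r$sens <= 1))
    expect_true(all(r$spec >= 0 & r$spec <= 1))
  }
  expect_error(rocAuc(1:5, rep(1, 5)), "both classes")
})

test_that("AUROC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(21)
  scores <- rnorm(60)
  labels <- rbinom(60, 1, plogis(scores))
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(rocAuc(scores, labels)$auc, ref, tolerance = 1e-12)
})

test_that("balanced-accuracy scan finds the exhaustive-threshold peak", {
  scan <- balancedAccuracyScan(c(1, 2, 3, 4), c(0, 0, 1, 1))
  expect_equal(scan$peak_accuracy, 1)
  expect_gt(scan$peak_threshold, 2)
  expect_lt(scan$peak_threshold, 3)
  # identical scores cannot beat chance
  expect_equal(balancedAccuracyScan(rep(2, 6),
                                    c(1, 0, 1, 0, 1, 0))$peak_accuracy, 0.5)
  set.seed(13)
  for (i in 1:25) {
    n <- sample(4:10, 1)
    labels <- c(0, 1, rbinom(n - 2, 1, 0.5))
    scores <- sample(seq(0, 1, 0.1), n, replace = TRUE)
    scan <- balancedAccuracyScan(scores, labels)
    fine <- seq(min(scores) - 0.2, max(scores) + 0.2, length.out = 4001)
    best <- max(vapply(fine, balanced_accuracy_at, numeric(1),
                       scores = scores, labels = labels))
    expect_equal(scan$peak_accuracy, best, tolerance = 1e-12)
    expect_equal(scan$peak_accuracy, max(scan$balanced_accuracy))
    expect_gte(scan$peak_accuracy, 0.5)
  }
})

test_that("centiles interpolate linearly and compare groups sensibly", {
  cs <- scoreCentiles(1:100)
  expect_equal(unname(cs$centiles), c(25.75, 50.5, 75.25))
  expect_equal(unname(scoreCentiles(rep(3, 10))$centiles), c(3, 3, 3))
  set.seed(3)
  a <- rnorm(1000)
  b <- rnorm(1000)  # same distribution: about half of b above a's median
  frac <- scoreCentiles(a, other = b)$frac_above_median
  expect_lt(abs(frac - 0.5), 0.05)
})

test_that("regression fits, bands and outlier flags behave as constructed", {
  # noiseless line: perfect correlation, no outliers
  fit <- regressionWithBand(1:30, 2 + 0.5 * (1:30))
  expect_equal(fit$pearson_r, 1, tolerance = 1e-12)
  expect_equal(fit$slope, 0.5, tolerance = 1e-12)
  expect_length(fit$outlier_ids, 0)
  # independent noise: ~1% of 500 points fall outside a 99% band
  set.seed(17)
  x <- rnorm(500); y <- rnorm(500)
  fit <- regressionWithBand(x, y)
  expect_lt(abs(fit$pearson_r), 0.15)
  n_out <- sum(y < fit$lower | y > fit$upper)
  expect_lte(n_out, 15)  # ~5 expected at 1%
  # a constructed extreme low point is flagged
  y2 <- -(1:20); names(y2) <- paste0("s", 1:20)
  y2["s10"] <- y2["s10"] - 50
  fit2 <- regressionWithBand(1:20, y2)
  expect_true("s10" %in% fit2$outlier_ids)
  expect_error(regressionWithBand(rep(1, 10), rnorm(10)), "constant")
})

test_that("rank-based group comparison separates what differs and only that", {
  set.seed(31)
  same <- rnorm(50)
  res <- rankGroupComparison(list(a = same, b = same))
  expect_gt(res$pairwise$p_value[1], 0.5)
  shifted <- rankGroupComparison(list(a = rnorm(50), b = rnorm(50) + 10))
  expect_lt(shifted$omnibus_p, 0.001)
  expect_lt(shifted$pairwise$p_value[1], 0.001)
  # three groups, one shifted: only its comparisons are significant
  three <- rankGroupComparison(list(a = rnorm(100), b = rnorm(100),
                                    c = rnorm(100) + 2))
  pw <- three$pairwise
  key <- paste(pw$group1, pw$group2)
  expect_gt(pw$p_value[key == "a b"], 0.05)
  expect_lt(pw$p_value[key == "a c"], 0.05)
  expect_lt(pw$p_value[key == "b c"], 0.05)
  expect_error(rankGroupComparison(list(a = numeric(), b = 1:3)),
               "non-empty")
})
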