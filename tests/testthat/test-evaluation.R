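test_that("error metrics follow their definitions on complete pairs", {
  expect_equal(mae(c(10, 12), c(10, 12)), 0)
  expect_equal(mae(c(10, 12), c(11, 12)), 0.5)
  # symmetry of MAE, asymmetry of MAPE
  x <- c(10, 20); y <- c(11, 19)
  expect_equal(mae(x, y), mae(y, x))
  expect_equal(mape(x, y), 7.5)
  expect_false(isTRUE(all.equal(mape(x, y), mape(y, x))))
  expect_equal(mape(x, x), 0)
  # NA epochs are dropped; no complete pairs -> absent metric, not 0
  expect_equal(mae(c(10, NA, 12), c(NA, 5, 13)), 1)
  expect_true(is.na(mae(c(NA, 1), c(2, NA))))
  expect_error(mape(c(0, 10), c(1, 10)), "undefined")
  # mae bounded by the largest difference; relative scaling identity
  set.seed(40)
  a <- runif(50, 10, 20); b <- a + rnorm(50)
  expect_lte(mae(a, b), max(abs(a - b)))
  expect_equal(mape(a, a * 1.04), 4, tolerance = 1e-9)
})

test_that("Spearman correlation equals the brute-force rank formula", {
  expect_equal(spearmanRho(1:10, (1:10)^3), 1)
  expect_equal(spearmanRho(1:10, -(1:10)^3), -1)
  expect_equal(spearmanRho(c(1, 2, 3, 4), c(1, 3, 2, 4)), 0.8)
  set.seed(41)
  for (i in 1:100) {
    x <- rnorm(20)
    y <- if (i %% 3 == 0) round(rnorm(20), 1) else rnorm(20)  # ties
    expect_equal(spearmanRho(x, y), spearmanOracle(x, y), tolerance = 1e-12)
  }
  expect_true(is.na(spearmanRho(c(1, 2), c(3, 4))))
  expect_true(is.na(spearmanRho(rep(1, 5), 1:5)))
  # invariance to epoch reordering
  x <- rnorm(30); y <- rnorm(30)
  o <- sample(30)
  expect_equal(spearmanRho(x[o], y[o]), spearmanRho(x, y))
})

test_that("recall percentage and count arithmetic reconcile", {
  r <- recallPercent(163999, 175425)
  expect_equal(round(r$percent, 2), 93.49)
  expect_equal(r$count, 163999)
  expect_equal(recallPercent(0, 100)$percent, 0)
  expect_equal(round(recallPercent(34963, 175425)$percent, 2), 19.93)
  expect_error(recallPercent(1, 0), "undefined")
  # counts and percentages reconcile at 2-decimal presentation rounding
  set.seed(42)
  for (i in 1:50) {
    tot <- sample(1000:200000, 1); cnt <- sample(0:tot, 1)
    expect_equal(round(recallPercent(cnt, tot)$percent, 2),
                 round(100 * cnt / tot, 2))
  }
})

test_that("the within-tolerance ratio uses a strict inequality", {
  expect_equal(withinTolerance(c(10, 12), c(10, 12))$percent, 100)
  wt <- withinTolerance(c(10, 10, 10), c(10.5, 11, 11.5))
  expect_equal(wt$percent, 100 / 3, tolerance = 1e-9)  # 1.0 excluded
  expect_equal(wt$count, 1)
  expect_equal(withinTolerance(c(1, 2), c(1.5, 2.5), tol = 0)$percent, 0)
})

test_that("uncovered duration measures the epoch-union complement", {
  grid <- epochGrid(300)          # 49 epochs
  all <- rep(TRUE, 49)
  expect_equal(uncoveredDuration(all, grid), 0)
  expect_equal(uncoveredDuration(!all, grid), 300)
  # only the epochs at 0 s and 120 s bear rates: 300 - 120 covered
  has <- rep(FALSE, 49); has[c(1, 25)] <- TRUE
  expect_equal(uncoveredDuration(has, grid), 180)
  # overlapping epochs do not double-count
  has2 <- rep(FALSE, 49); has2[1:3] <- TRUE   # 0-70 s covered
  expect_equal(uncoveredDuration(has2, grid), 230)
})

test_that("Bland-Altman limits are mean +/- 1.96 sample SD", {
  ba <- blandAltman(c(10, 10), c(10, 10))
  expect_equal(ba$mean_diff, 0)
  expect_equal(ba$loa_low, 0)
  expect_equal(ba$pct_below + ba$pct_above, 0)
  # diffs -1 and +1: sd = sqrt(2), limits +/- 2.772
  ba <- blandAltman(c(10, 12), c(11, 11))
  expect_equal(ba$mean_diff, 0)
  expect_equal(ba$loa_high, 1.96 * sqrt(2), tolerance = 1e-9)
  expect_equal(ba$loa_high, 2.772, tolerance = 1e-3)
  # sign convention: reference minus radar
  ba <- blandAltman(c(10, 10), c(12, 12))
  expect_equal(ba$mean_diff, -2)
  set.seed(43)
  ba <- blandAltman(rnorm(500, 12), rnorm(500, 12))
  expect_lte(ba$pct_below + ba$pct_above, 100)
  expect_true(is.na(blandAltman(c(1, NA), c(NA, 2))$mean_diff))
})

test_that("the agreement report assembles all metrics coherently", {
  grid <- epochGrid(300)
  set.seed(44)
  ref <- runif(49, 12, 18); est <- ref + rnorm(49, 0, 0.4)
  ref[5:8] <- NA; est[10:20] <- NA
  rep1 <- agreementReport(ref, est, grid)
  expect_equal(rep1$n_total_epochs, 49)
  expect_equal(rep1$recall_psg$count, 45)
  expect_equal(rep1$recall_radar$count, 38)
  expect_equal(rep1$mae, mae(ref, est))
  expect_equal(rep1$spearman_rho, spearmanRho(ref, est))
  expect_equal(rep1$uncovered_radar_s,
               uncoveredDuration(!is.na(est), grid))
  # restricting the analyzed mask drops those epochs from every metric
  analyzed <- rep(TRUE, 49); analyzed[1:10] <- FALSE
  rep2 <- agreementReport(ref, est, grid, analyzed = analyzed)
  expect_equal(rep2$n_total_epochs, 39)
  expect_equal(rep2$recall_psg$count, sum(!is.na(ref[11:49])))
})
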