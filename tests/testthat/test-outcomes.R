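test_that("Kaplan-Meier median follows the product-limit definition", {
  expect_equal(kmCurve(c(1, 2, 3), c(TRUE, TRUE, TRUE))$median, 2)
  expect_true(is.na(kmCurve(c(5, 6, 7), rep(FALSE, 3))$median))
  expect_error(kmCurve(numeric(0), logical(0)), "empty")
})

test_that("KM with no censoring equals the empirical survival function", {
  set.seed(2)
  t <- rexp(40, 0.1)
  km <- kmCurve(t, rep(TRUE, 40))
  emp <- vapply(km$time, function(x) mean(t > x), numeric(1))
  expect_equal(km$surv, emp)
})

test_that("KM agrees with an independent product-limit oracle on random data", {
  for (seed in 1:100) {
    set.seed(seed)
    n <- sample(5:30, 1)
    t <- round(rexp(n, 0.1), 1) + 0.1
    e <- runif(n) < 0.7
    km <- kmCurve(t, e)
    orc <- kmOracle(t, e)
    expect_equal(unname(km$median), orc$median)
    if (any(e)) {
      idx <- match(orc$time, km$time)
      expect_equal(km$surv[idx], orc$surv)
    }
  }
})

test_that("the guided 17-patient cohort reproduces its printed endpoints", {
  co <- guidedCohort()
  r <- clinicalRecords(co)
  expect_equal(nrow(r), 17)
  expect_equal(sum(r$overall_response %in% c("CR", "PR")), 15)
  expect_equal(sum(r$overall_response == "PD"), 0)
  expect_equal(sum(r$ongoing), 8)
  km <- kmCurve(r$pfs_weeks, !r$ongoing)
  expect_equal(km$median, 22.6)
  # verified against the hand-rolled product-limit oracle
  expect_equal(kmOracle(r$pfs_weeks, !r$ongoing)$median, 22.6)
})

test_that("log-rank is null on identical groups and robust to degenerate input", {
  set.seed(3)
  t <- rexp(30, 0.2); e <- rep(TRUE, 30)
  lr <- logrankHR(t, e, t, e)
  expect_lt(lr$chisq, 1e-10)
  expect_equal(lr$hr, 1, tolerance = 1e-6)
  # one group entirely censored early: no crash, finite statistic
  lr2 <- logrankHR(t, e, rep(0.01, 10), rep(FALSE, 10))
  expect_true(is.finite(lr2$chisq))
})

test_that("log-rank chi-square matches a hand-rolled Mantel-Cox oracle", {
  for (seed in 1:100) {
    set.seed(seed)
    n1 <- sample(5:20, 1); n2 <- sample(5:20, 1)
    t1 <- round(rexp(n1, 0.1), 1) + 0.1; e1 <- runif(n1) < 0.8
    t2 <- round(rexp(n2, 0.2), 1) + 0.1; e2 <- runif(n2) < 0.8
    if (!any(e1) && !any(e2)) next
    got <- logrankHR(t1, e1, t2, e2)
    expect_equal(got$chisq, logrankOracle(t1, e1, t2, e2)$chisq,
                 tolerance = 1e-8)
  }
})

test_that("a true hazard ratio of 3 is recovered at n = 200 per arm", {
  hrs <- vapply(1:50, function(s) {
    co <- simulateClinical(200, hazard_ratio = 3, seed = s)
    r <- clinicalRecords(co)
    logrankHR(r$prior_pfs_weeks, rep(TRUE, 200), r$pfs_weeks, !r$ongoing)$hr
  }, numeric(1))
  expect_gte(mean(hrs), 2.5)
  expect_lte(mean(hrs), 3.6)
})

test_that("one-sided McNemar reproduces the continuity-corrected form", {
  got <- mcnemarOneSided(b = 0, c = 11)
  expect_equal(got$statistic, 100 / 11)
  expect_equal(got$p, mcnemarOracle(0, 11))
  expect_equal(round(got$p, 4), 0.0013)
  expect_equal(mcnemarOneSided(3, 3)$p, 0.5)
  expect_equal(mcnemarOneSided(0, 0)$p, 1)
  # statistic symmetric in (b, c); p directional
  expect_equal(mcnemarOneSided(2, 9)$statistic, mcnemarOneSided(9, 2)$statistic)
  expect_gt(mcnemarOneSided(9, 2)$p, 0.5)
  # continuity correction clamps at |b - c| <= 1
  expect_equal(mcnemarOneSided(4, 5)$statistic, 0)
})

test_that("McNemar matches its oracle over random tables", {
  for (seed in 1:300) {
    set.seed(seed)
    b <- rpois(1, 3); c <- rpois(1, 3)
    expect_equal(mcnemarOneSided(b, c)$p, mcnemarOracle(b, c))
  }
})

test_that("cross-product odds ratio with sentinels and correction", {
  expect_equal(contingencyOddsRatio(15, 17, 4, 17), 24.375)
  expect_equal(contingencyOddsRatio(5, 10, 5, 10), 1.0)
  expect_equal(contingencyOddsRatio(10, 10, 4, 17), Inf)
  expect_true(is.finite(contingencyOddsRatio(10, 10, 4, 17, haldane = TRUE)))
  # transposing the groups inverts the odds ratio
  for (seed in 1:100) {
    set.seed(seed)
    n1 <- sample(5:30, 1); n2 <- sample(5:30, 1)
    r1 <- sample(1:(n1 - 1), 1); r2 <- sample(1:(n2 - 1), 1)
    expect_equal(contingencyOddsRatio(r1, n1, r2, n2),
                 1 / contingencyOddsRatio(r2, n2, r1, n1))
    expect_equal(contingencyOddsRatio(r1, n1, r2, n2),
                 (r1 * (n2 - r2)) / ((n1 - r1) * r2))
  }
})

test_that("paired cells reconstruct from printed margins", {
  cells <- pairedTableFromMargins(15, 4, 17, discordantPriorOnly = 0)
  expect_equal(cells, list(a = 4, b = 0, c = 11, d = 2))
  expect_error(pairedTableFromMargins(2, 10, 5), "inconsistent")
})

test_that("PFS-ratio analysis uses an inclusive 1.3 threshold and exact test", {
  r <- pfsRatioAnalysis(c(13, 5, 20), c(10, 10, 10))
  expect_equal(r$ratios, c(1.3, 0.5, 2.0))
  expect_equal(r$n_benefit, 2)
  none <- pfsRatioAnalysis(c(1, 2), c(10, 10))
  expect_equal(none$fraction, 0)
  expect_false(none$reject_null)
  # 12 of 17 against a 15% null: overwhelming evidence
  many <- pfsRatioAnalysis(c(rep(2, 12), rep(1, 5)), rep(1, 17))
  expect_lt(many$p, 1e-5)
  expect_equal(many$p, binomTailOracle(12, 17, 0.15))
  expect_true(many$reject_null)
})

test_that("i-PCY association recovers monotone, null and simulated links", {
  ipcy <- c(-2, -1, 0, 1, 2, 3, 4, 5)
  ordResp <- c(1, 1, 2, 2, 3, 3, 4, 4)
  a <- ipcyOutcomeAssociation(ipcy, ordResp)
  expect_gt(a$r, 0.95)
  expect_equal(a$accuracy, 1.0)
  expect_equal(a$auroc, 1.0)
  # independence: near-zero correlation at n = 1000
  set.seed(77)
  x <- rnorm(1000); y <- sample(1:4, 1000, replace = TRUE)
  expect_lt(abs(ipcyOutcomeAssociation(x, y)$r), 0.07)
  # a simulated positive link is recovered above chance
  r <- clinicalRecords(simulateClinical(200, ipcy_beta = 1.5, seed = 5))
  got <- ipcyOutcomeAssociation(r$i_pcy, r$ordinal_response)
  expect_gt(got$r, 0.2)
  expect_gt(got$auroc, 0.6)
})

test_that("outcomeSummary wires endpoints, OR and McNemar together", {
  s <- outcomeSummary(guidedCohort(), respondersPrior = 4)
  expect_equal(s$responders, 15)
  expect_equal(s$odds_ratio, 24.375)
  expect_equal(s$mcnemar$p, mcnemarOracle(0, 11))
  expect_equal(s$paired_cells$c, 11)
})
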