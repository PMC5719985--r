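test_that("auroc follows the Mann-Whitney convention with 0.5 ties", {
  expect_equal(auroc(c(0.2, 0.4), c(0.5, 0.3), positiveSide = "low"), 0.75)
  expect_equal(auroc(c(5, 6), c(1, 2)), 1.0)
  expect_equal(auroc(c(1, 2, 3), c(1, 2, 3)), 0.5)
  expect_equal(auroc(1, 1), 0.5)
})

test_that("auroc matches pair enumeration and pROC on random samples", {
  for (seed in 1:50) {
    set.seed(seed)
    pos <- round(rnorm(sample(2:8, 1)), 1)
    neg <- round(rnorm(sample(2:8, 1)), 1)
    expect_equal(auroc(pos, neg), aurocOracle(pos, neg))
  }
  skip_if_not_installed("pROC")
  set.seed(1)
  pos <- rnorm(20, 1); neg <- rnorm(25)
  pr <- pROC::roc(response = rep(c(1, 0), c(20, 25)),
                  predictor = c(pos, neg), quiet = TRUE, direction = "<")
  expect_equal(auroc(pos, neg), as.numeric(pROC::auc(pr)))
})

test_that("the per-point fit places thresholds between separated classes", {
  M <- matrix(c(0.3, 0.4, 0.8, 0.9), ncol = 1)
  lab <- rep(c("complete_remission", "non_responder"), each = 2)
  m <- fitHyperplane(M, labels = lab)
  expect_equal(m@threshold, 0.6)
  expect_equal(m@orientation, 1L)
  expect_equal(m@weight, 1.0)
})

test_that("an uninformative point gets weight 0.5 and weights stay >= 0.5", {
  M <- matrix(c(1, 2, 3, 4, 1, 2, 3, 4), ncol = 1)
  lab <- rep(c("complete_remission", "non_responder"), each = 4)
  m <- fitHyperplane(M, labels = lab)
  expect_equal(m@weight, 0.5)
  set.seed(2)
  M2 <- matrix(rnorm(20 * 12), 20, 12)
  lab2 <- rep(c("complete_remission", "non_responder"), each = 10)
  m2 <- fitHyperplane(M2, labels = lab2)
  expect_true(all(m2@weight >= 0.5))
})

test_that("fitting requires both classes", {
  M <- matrix(rnorm(10), 5, 2)
  expect_error(fitHyperplane(M, labels = rep("non_responder", 5)),
               "both classes")
})

test_that("integrated scores weight per-point sides by AUROC", {
  toy <- new("HyperplaneModel", threshold = c(1, 1), orientation = c(1L, 1L),
             weight = c(1, 0.5), readout = "rbf", cut = 0)
  # below both thresholds: responder side everywhere
  expect_equal(integratedResponseScore(c(0.5, 0.5), toy)$score, 1)
  expect_equal(integratedResponseScore(c(1.5, 1.5), toy)$score, -1)
  # mixed: (1 - 0.5) / 1.5
  expect_equal(integratedResponseScore(c(0.5, 1.5), toy)$score, 1 / 3)
})

test_that("integrated scores are bounded and flip under label swap", {
  set.seed(5)
  M <- matrix(rnorm(16 * 20, 1), 16, 20)
  M[1:8, ] <- M[1:8, ] - 0.4
  lab <- rep(c("complete_remission", "non_responder"), each = 8)
  swapped <- rep(c("non_responder", "complete_remission"), each = 8)
  m1 <- fitHyperplane(M, labels = lab)
  m2 <- fitHyperplane(M, labels = swapped)
  for (i in 1:16) {
    s1 <- integratedResponseScore(M[i, ], m1)$score
    s2 <- integratedResponseScore(M[i, ], m2)$score
    expect_lte(abs(s1), 1)
    expect_equal(s1, -s2)
  }
})

test_that("an added uninformative point obeys the dilution bound", {
  set.seed(6)
  m <- new("HyperplaneModel", threshold = rep(1, 10),
           orientation = rep(1L, 10), weight = runif(10, 0.5, 1),
           readout = "rbf", cut = 0)
  v <- runif(10, 0.5, 1.5)
  base <- integratedResponseScore(v, m)$score
  m2 <- new("HyperplaneModel", threshold = c(m@threshold, 1),
            orientation = c(m@orientation, 1L), weight = c(m@weight, 0.5),
            readout = "rbf", cut = 0)
  W <- sum(m@weight)
  for (side in c(0.9, 1.1)) {
    s2 <- integratedResponseScore(c(v, side), m2)$score
    sNew <- if (side < 1) 1 else -1
    # exact dilution identity: delta = 0.5 (s_new - score) / (W + 0.5)
    expect_equal(s2 - base, 0.5 * (sNew - base) / (W + 0.5))
    expect_lt(abs(s2 - base), 1 / (W + 0.5))
  }
})

test_that("leave-k-out enumerates all held-out combinations", {
  coh <- separatedCohort(nPerClass = 4)
  cv <- leaveKOutCV(coh, k_per_class = 1)
  expect_equal(cv$n_runs, 16)  # C(4,1)^2
  cv2 <- leaveKOutCV(coh, k_per_class = 2)
  expect_equal(cv2$n_runs, 36)  # C(4,2)^2
  expect_error(leaveKOutCV(coh, k_per_class = 4), "k_per_class")
  expect_error(leaveKOutCV(coh, k_per_class = 0), "k_per_class")
})

test_that("perfect separation gives accuracy and AUROC 1", {
  coh <- separatedCohort(nPerClass = 5, gap = 0.6)
  cv <- leaveKOutCV(coh, k_per_class = 2)
  expect_equal(cv$mean_accuracy, 1.0)
  expect_equal(cv$auroc, 1.0)
})

test_that("held-out patients never influence the trained model", {
  coh <- separatedCohort(nPerClass = 4, nPts = 6)
  M <- patientMeans(coh, "rbf")
  isResp <- cohortLabels(coh) == "complete_remission"
  hold <- c(1, 5)
  train <- setdiff(1:8, hold)
  ref <- fitHyperplane(M[train, ], labels = ifelse(isResp[train],
                                                   "complete_remission",
                                                   "non_responder"))
  poisoned <- M
  poisoned[hold, ] <- 1e6
  got <- fitHyperplane(poisoned[train, ],
                       labels = ifelse(isResp[train], "complete_remission",
                                       "non_responder"))
  expect_identical(ref@threshold, got@threshold)
  expect_identical(ref@weight, got@weight)
  # and CV accuracies on runs not involving a poisoned patient are unchanged
  cvRef <- leaveKOutCV(coh, k_per_class = 1)
  cohP <- coh
  cohP@assays$rbf[1, , ] <- cohP@assays$rbf[1, , ] + 100
  cvP <- leaveKOutCV(cohP, k_per_class = 1)
  # runs are ordered responder-combo x non-responder combo; patient 1 is
  # held out in the first C(4,1) block
  untouched <- 5:16
  expect_equal(cv2 <- cvP$accuracies[untouched], cvRef$accuracies[untouched])
})

test_that("readout comparison runs every assay on the same cohort", {
  coh <- separatedCohort(nPerClass = 3, nPts = 8)
  coh@assays$total_cells <- coh@assays$rbf
  coh@assays$total_blasts <- coh@assays$rbf
  rc <- readoutComparison(coh, k_per_class = 1)
  expect_equal(nrow(rc), 3)
  # identical readout matrices give identical accuracies
  expect_equal(rc$accuracy[1], rc$accuracy[2])
  expect_equal(rc$accuracy[2], rc$accuracy[3])
})

test_that("group means come with one-sided tests in the right direction", {
  coh <- separatedCohort(nPerClass = 5, nPts = 12, gap = 0.5)
  gm <- groupMeanHeatmap(coh)
  expect_equal(nrow(gm), 12)
  expect_true(all(gm$p_one_sided < 0.01))  # CR shifted down by >> 2 SD
  # identical groups: p ~ 0.5
  cohNull <- separatedCohort(nPerClass = 5, nPts = 12, gap = 0)
  gmNull <- groupMeanHeatmap(cohNull)
  expect_gt(mean(gmNull$p_one_sided), 0.25)
  expect_lt(mean(gmNull$p_one_sided), 0.75)
})

test_that("one-sided group p-values fall with dose along a simulated axis", {
  coh <- simulateAmlCohort(cohortSimConfig(effect_gap = 0.4, seed = 3))
  gm <- groupMeanHeatmap(coh, "rbf")
  pts <- attr(coh, "truth")$points
  doseSum <- pts$c1 + pts$c2 + pts$c3
  # stronger combined dose -> stronger CR-vs-NR reduction in expectation
  expect_lt(cor(doseSum, log10(gm$p_one_sided + 1e-300)), -0.3)
})
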