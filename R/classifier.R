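#' Area under the ROC curve by the Mann-Whitney convention
#'
#' Probability that a randomly chosen positive ranks on the positive side of
#' a randomly chosen negative; tied pairs count 0.5. \code{positiveSide}
#' states whether positives are expected at high or low values.
#'
#' @param valuesPos,valuesNeg numeric samples for the two classes
#' @param positiveSide \code{"high"} (default) or \code{"low"}
#' @return AUROC in [0, 1]
#' @examples
#' auroc(c(0.2, 0.4), c(0.5, 0.3), positiveSide = "low")  # 0.75
#' @export
auroc <- function(valuesPos, valuesNeg, positiveSide = c("high", "low")) {
  positiveSide <- match.arg(positiveSide)
  nP <- length(valuesPos); nN <- length(valuesNeg)
  stopifnot(nP >= 1, nN >= 1)
  r <- rank(c(valuesPos, valuesNeg))
  u <- sum(r[seq_len(nP)]) - nP * (nP + 1) / 2
  a <- u / (nP * nN)
  if (positiveSide == "low") 1 - a else a
}

# Core per-point fit on a patients x points matrix of training means.
fitHyperplaneCore <- function(M, isResp) {
  nPts <- ncol(M)
  nR <- sum(isResp); nN <- sum(!isResp); ntot <- nR + nN
  if (nR == 0 || nN == 0) stop("training set must contain both classes")
  respMean <- colMeans(M[isResp, , drop = FALSE])
  nonMean <- colMeans(M[!isResp, , drop = FALSE])
  sigma <- ifelse(respMean <= nonMean, 1L, -1L)
  thr <- numeric(nPts); wt <- numeric(nPts)
  for (j in seq_len(nPts)) {
    v <- M[, j]
    r <- rank(v)
    aucHigh <- (sum(r[isResp]) - nR * (nR + 1) / 2) / (nR * nN)
    a <- if (sigma[j] == 1L) 1 - aucHigh else aucHigh
    if (a < 0.5) { sigma[j] <- -sigma[j]; a <- 1 - a }
    wt[j] <- a
    ord <- order(v)
    vs <- v[ord]
    cumR <- cumsum(isResp[ord])
    cand <- which(diff(vs) > 0)
    mid <- (respMean[j] + nonMean[j]) / 2
    if (!length(cand)) { thr[j] <- mid; next }
    cumN <- seq_len(ntot)[cand] - cumR[cand]
    accBelowResp <- (cumR[cand] + (nN - cumN)) / ntot
    acc <- if (sigma[j] == 1L) accBelowResp else 1 - accBelowResp
    tcand <- (vs[cand] + vs[cand + 1]) / 2
    best <- which(acc >= max(acc) - 1e-12)
    # among accuracy ties prefer the candidate nearest the class-mean midpoint
    pick <- best[order(abs(tcand[best] - mid), tcand[best])][1]
    thr[j] <- tcand[pick]
  }
  list(threshold = thr, orientation = as.integer(sigma), weight = wt)
}

integratedScoresMatrix <- function(M, thr, sigma, wt) {
  # responder side: sigma * (value - threshold) < 0
  comp <- sweep(sweep(M, 2, sigma, `*`), 2, sigma * thr, `-`)
  s <- ifelse(comp < 0, 1, -1)
  as.numeric(s %*% wt) / sum(wt)
}

#' Fit the AUROC-weighted separating surface on a training cohort
#'
#' For every matrix point: the orientation marks the lower-value side as
#' responder-like iff the responders' class mean is below the
#' non-responders'; the threshold is the midpoint between the two adjacent
#' training values that maximises training accuracy at that point (accuracy
#' ties resolved towards the midpoint of the class means); the weight is the
#' point's AUROC, re-oriented so weights always lie in [0.5, 1]. The model
#' also stores the training cut on integrated response scores (midpoint of
#' the class-mean scores, falling back to 0 when the training class means do
#' not separate) used to classify new patients.
#'
#' @param cohort a [DrugMatrixCohort-class] (or a plain patients x points
#'   matrix, in which case \code{labels} must be given)
#' @param readout which assay to fit on
#' @param labels optional factor/character of per-patient labels when
#'   \code{cohort} is a matrix (\code{"complete_remission"} = responder)
#' @return a [HyperplaneModel-class]
#' @export
fitHyperplane <- function(cohort, readout = "rbf", labels = NULL) {
  if (is(cohort, "DrugMatrixCohort")) {
    M <- patientMeans(cohort, readout)
    isResp <- cohortLabels(cohort) == "complete_remission"
  } else {
    M <- as.matrix(cohort)
    if (is.null(labels)) stop("labels required when fitting on a matrix")
    isResp <- as.character(labels) == "complete_remission"
  }
  core <- fitHyperplaneCore(M, isResp)
  sc <- integratedScoresMatrix(M, core$threshold, core$orientation, core$weight)
  mR <- mean(sc[isResp]); mN <- mean(sc[!isResp])
  cut <- if (mR > mN) (mR + mN) / 2 else 0
  new("HyperplaneModel", threshold = core$threshold,
      orientation = core$orientation, weight = core$weight,
      readout = readout, cut = cut)
}

#' Integrated response score of one patient profile
#'
#' Scores each matrix point +1 when the patient's replicate-mean value lies
#' on the responder side of the fitted threshold and -1 otherwise, and
#' averages the indicators weighted by the per-point AUROC weights. The
#' result is bounded in [-1, 1]; positive scores are responder-like.
#'
#' @param values numeric vector of the patient's per-point replicate means
#' @param model a [HyperplaneModel-class]
#' @return list with \code{score} and the per-point signs \code{s}
#' @export
integratedResponseScore <- function(values, model) {
  stopifnot(length(values) == length(model@threshold))
  onResp <- model@orientation * (values - model@threshold) < 0
  s <- ifelse(onResp, 1, -1)
  list(score = sum(model@weight * s) / sum(model@weight), s = s)
}

#' Leave-k-out cross-validated classification of clinical response
#'
#' Enumerates every combination of \code{k_per_class} held-out patients from
#' each class (the 10+10 design with k=2 gives C(10,2)^2 = 2025 runs). Each
#' run refits the separating surface and its classification cut on the
#' remaining patients only, then classifies the held-out patients by whether
#' their integrated response score exceeds the training cut. ROC curves of
#' the held-out scores are averaged vertically over a fixed
#' false-positive-rate grid.
#'
#' @param cohort a [DrugMatrixCohort-class]
#' @param readout which assay to classify on
#' @param k_per_class patients held out per class and run
#' @param fprGrid false-positive-rate grid for vertical ROC averaging
#' @return list with \code{n_runs}, \code{accuracies} (per run),
#'   \code{mean_accuracy}, \code{roc} (data.frame fpr/tpr of the averaged
#'   curve), \code{auroc} (area under the averaged curve)
#' @export
leaveKOutCV <- function(cohort, readout = "rbf", k_per_class = 2,
                        fprGrid = seq(0, 1, length.out = 101)) {
  M <- patientMeans(cohort, readout)
  isResp <- cohortLabels(cohort) == "complete_remission"
  iR <- which(isResp); iN <- which(!isResp)
  if (k_per_class < 1 || k_per_class >= length(iR) || k_per_class >= length(iN))
    stop("k_per_class must be >= 1 and smaller than each class size")
  combR <- utils::combn(iR, k_per_class)
  combN <- utils::combn(iN, k_per_class)
  nRuns <- ncol(combR) * ncol(combN)
  accs <- numeric(nRuns)
  tprMat <- matrix(NA_real_, nRuns, length(fprGrid))
  run <- 0L
  for (a in seq_len(ncol(combR))) {
    for (b in seq_len(ncol(combN))) {
      run <- run + 1L
      hold <- c(combR[, a], combN[, b])
      train <- setdiff(seq_len(nrow(M)), hold)
      core <- fitHyperplaneCore(M[train, , drop = FALSE], isResp[train])
      scTrain <- integratedScoresMatrix(M[train, , drop = FALSE],
                                        core$threshold, core$orientation,
                                        core$weight)
      mR <- mean(scTrain[isResp[train]]); mN <- mean(scTrain[!isResp[train]])
      cut <- if (mR > mN) (mR + mN) / 2 else 0
      scHold <- integratedScoresMatrix(M[hold, , drop = FALSE],
                                       core$threshold, core$orientation,
                                       core$weight)
      pred <- scHold > cut
      accs[run] <- mean(pred == isResp[hold])
      tprMat[run, ] <- rocStep(scHold, isResp[hold], fprGrid)
    }
  }
  tpr <- colMeans(tprMat)
  aucAvg <- sum(diff(fprGrid) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  list(n_runs = nRuns, accuracies = accs, mean_accuracy = mean(accs),
       roc = data.frame(fpr = fprGrid, tpr = tpr), auroc = aucAvg)
}

# TPR of the empirical ROC step function at each FPR grid value.
rocStep <- function(scores, isPos, fprGrid) {
  nP <- sum(isPos); nN <- sum(!isPos)
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- c(0, vapply(thr, function(t) sum(scores[isPos] >= t) / nP, 1))
  fpr <- c(0, vapply(thr, function(t) sum(scores[!isPos] >= t) / nN, 1))
  vapply(fprGrid, function(g) max(tpr[fpr <= g + 1e-12]), numeric(1))
}

#' Compare classification power of the three cellular readouts
#'
#' Runs [leaveKOutCV()] for the relative blast fraction, the DMSO-relative
#' total cell count, and the DMSO-relative total blast count on the same
#' cohort. On screens where only the marker-positive subpopulation carries
#' the class signal and blast fractions vary between patients, the
#' within-well-normalised RBF classifies best.
#'
#' @param cohort a [DrugMatrixCohort-class]
#' @param k_per_class held-out patients per class
#' @return data.frame with one row per readout: \code{readout},
#'   \code{accuracy}, \code{auroc}
#' @export
readoutComparison <- function(cohort, k_per_class = 2) {
  readouts <- names(cohort@assays)
  res <- lapply(readouts, function(r) {
    cv <- leaveKOutCV(cohort, readout = r, k_per_class = k_per_class)
    data.frame(readout = r, accuracy = cv$mean_accuracy, auroc = cv$auroc,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Per-matrix-point class means and one-sided group comparison
#'
#' For every matrix point: class means and standard errors, and a one-sided
#' Welch t-test for a reduction in the complete-remission group relative to
#' the non-responders.
#'
#' @param cohort a [DrugMatrixCohort-class]
#' @param readout which assay to compare
#' @return data.frame per matrix point: \code{point}, \code{mean_cr},
#'   \code{se_cr}, \code{mean_nr}, \code{se_nr}, \code{p_one_sided}
#' @export
groupMeanHeatmap <- function(cohort, readout = "rbf") {
  M <- patientMeans(cohort, readout)
  isResp <- cohortLabels(cohort) == "complete_remission"
  se <- function(x) stats::sd(x) / sqrt(length(x))
  out <- lapply(seq_len(ncol(M)), function(j) {
    cr <- M[isResp, j]; nr <- M[!isResp, j]
    p <- if (stats::sd(cr) == 0 && stats::sd(nr) == 0) {
      if (mean(cr) < mean(nr)) 0 else if (mean(cr) > mean(nr)) 1 else 0.5
    } else stats::t.test(cr, nr, alternative = "less")$p.value
    data.frame(point = j, mean_cr = mean(cr), se_cr = se(cr),
               mean_nr = mean(nr), se_nr = se(nr), p_one_sided = p)
  })
  do.call(rbind, out)
}

#' Relabel a cohort with permuted class labels
#'
#' Utility for null calibration: returns a copy of the cohort whose labels
#' are a random permutation of the originals.
#'
#' @param cohort a [DrugMatrixCohort-class]
#' @param seed RNG seed
#' @return a [DrugMatrixCohort-class]
#' @export
permuteLabels <- function(cohort, seed = 1L) {
  set.seed(seed)
  cohort@labels <- sample(cohort@labels)
  cohort
}
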