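#' Read a long-format well count table
#'
#' Reads a CSV with one row per well x marker carrying the single-cell derived
#' counts of viable marker-positive and marker-negative cells, and validates
#' it into a [WellScreen-class]. Each patient must have at least one DMSO
#' vehicle-control well, since control wells define the normalisation baseline
#' for relative blast fractions.
#'
#' @param path path to a CSV file with header columns \code{patient_id},
#'   \code{plate_id}, \code{well}, \code{drug}, \code{concentration_um},
#'   \code{replicate}, \code{marker}, \code{n_viable_marker_pos},
#'   \code{n_viable_marker_neg}, \code{n_total_cells}.
#' @return a \code{WellScreen}
#' @examples
#' csv <- tempfile(fileext = ".csv")
#' write.csv(data.frame(
#'   patient_id = "P1", plate_id = "plate1", well = c("A1", "A2", "A3"),
#'   drug = c("DMSO", "DMSO", "bortezomib"), concentration_um = c(0, 0, 10),
#'   replicate = 1, marker = "CD34",
#'   n_viable_marker_pos = c(400, 410, 150),
#'   n_viable_marker_neg = c(600, 590, 650),
#'   n_total_cells = c(1100, 1050, 1000)), csv, row.names = FALSE)
#' scr <- readWellTable(csv)
#' scr
#' @export
readWellTable <- function(path) {
  w <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(WELL_TABLE_COLUMNS, names(w))
  if (length(missing))
    stop(sprintf("well table schema error: missing column(s) %s",
                 paste(missing, collapse = ", ")))
  WellScreen(w)
}

#' Construct a WellScreen from a data.frame
#'
#' @param wells data.frame in the [readWellTable()] schema.
#' @return a validated \code{WellScreen}
#' @export
WellScreen <- function(wells) {
  wells <- as.data.frame(wells, stringsAsFactors = FALSE)
  obj <- new("WellScreen", wells = wells)
  # control coverage: every patient needs DMSO wells to normalise against
  for (p in unique(wells$patient_id)) {
    sub <- wells[wells$patient_id == p, ]
    if (!any(sub$drug == CONTROL_DRUG))
      stop(sprintf("control-missing error: patient %s has no %s wells",
                   p, CONTROL_DRUG))
  }
  obj
}

#' Viable marker-positive fraction per well row
#' @keywords internal
viableFraction <- function(pos, neg) {
  tot <- pos + neg
  ifelse(tot > 0, pos / tot, NA_real_)
}

#' Relative blast fraction for one patient x marker x drug
#'
#' The relative blast fraction (RBF) of a drug-treated well is the fraction
#' of marker-positive viable cells in that well divided by the mean fraction
#' of marker-positive viable cells across the patient's DMSO control wells.
#' RBF 1 means no on-target effect; RBF < 1 on-target depletion of the blast
#' population; RBF > 1 relative blast enrichment (ex vivo chemoresistance).
#' Values are not capped (capping at 1.2 is a display convention only).
#'
#' Per-well RBFs are averaged over technical replicates within each
#' concentration first, then averaged (unweighted) over concentrations.
#' Wells whose viable total (pos + neg) is zero have an undefined fraction and
#' are excluded with a warning.
#'
#' @param screen a [WellScreen-class]
#' @param patient,marker,drug which patient x marker x drug to score
#' @return list with \code{rbf_mean}, \code{rbf_per_replicate} (per drug well,
#'   NA for excluded wells), \code{rbf_by_concentration}, \code{control_mean_fraction}
#' @examples
#' scr <- WellScreen(data.frame(
#'   patient_id = "P1", plate_id = "pl", well = c("A1", "A2", "B1"),
#'   drug = c("DMSO", "DMSO", "drugX"), concentration_um = c(0, 0, 1),
#'   replicate = 1, marker = "CD34",
#'   n_viable_marker_pos = c(40, 40, 20), n_viable_marker_neg = c(60, 60, 80),
#'   n_total_cells = c(110, 110, 105)))
#' computeRBF(scr, "P1", "CD34", "drugX")$rbf_mean  # 0.25 / 0.40 = 0.625
#' @export
computeRBF <- function(screen, patient, marker, drug) {
  w <- screen@wells
  w <- w[w$patient_id == patient & w$marker == marker, , drop = FALSE]
  ctl <- w[w$drug == CONTROL_DRUG, , drop = FALSE]
  trt <- w[w$drug == drug, , drop = FALSE]
  if (!nrow(ctl)) stop(sprintf("no %s control wells for patient %s marker %s",
                               CONTROL_DRUG, patient, marker))
  if (!nrow(trt)) stop(sprintf("no wells for drug %s (patient %s, marker %s)",
                               drug, patient, marker))
  ctlFrac <- viableFraction(ctl$n_viable_marker_pos, ctl$n_viable_marker_neg)
  ctlMean <- mean(ctlFrac, na.rm = TRUE)
  if (!is.finite(ctlMean) || ctlMean <= 0)
    stop(sprintf("control mean fraction undefined or zero for patient %s marker %s",
                 patient, marker))
  frac <- viableFraction(trt$n_viable_marker_pos, trt$n_viable_marker_neg)
  if (anyNA(frac))
    warning(sprintf(
      "%d well(s) with zero viable cells excluded from RBF (drug %s, patient %s)",
      sum(is.na(frac)), drug, patient))
  rbf <- frac / ctlMean
  if (all(is.na(rbf)))
    return(list(rbf_mean = NA_real_, rbf_per_replicate = rbf,
                rbf_by_concentration = NULL, control_mean_fraction = ctlMean))
  byConc <- tapply(rbf, trt$concentration_um, mean, na.rm = TRUE)
  byConc <- byConc[is.finite(byConc)]
  list(rbf_mean = mean(byConc),
       rbf_per_replicate = as.numeric(rbf),
       rbf_by_concentration = byConc,
       control_mean_fraction = ctlMean)
}

#' Per-drug significance against vehicle controls
#'
#' Two-tailed Welch two-sample t-test of a drug's per-well RBF values against
#' the per-well control RBFs (whose mean is 1 by construction of the
#' normalisation). Fewer than two values on either side yields a missing
#' p-value and a non-significant call.
#'
#' @param drugRbfs numeric, per-well RBFs for the drug
#' @param controlRbfs numeric, per-well RBFs of the DMSO wells
#' @param alpha significance level (default 0.05, uncorrected)
#' @return list with \code{p_value} and \code{significant}
#' @export
drugSignificance <- function(drugRbfs, controlRbfs, alpha = 0.05) {
  drugRbfs <- drugRbfs[is.finite(drugRbfs)]
  controlRbfs <- controlRbfs[is.finite(controlRbfs)]
  if (length(drugRbfs) < 2 || length(controlRbfs) < 2)
    return(list(p_value = NA_real_, significant = FALSE))
  if (stats::sd(drugRbfs) == 0 && stats::sd(controlRbfs) == 0) {
    # degenerate: identical constants on both sides
    p <- if (isTRUE(all.equal(mean(drugRbfs), mean(controlRbfs)))) 1 else 0
    return(list(p_value = p, significant = p < alpha))
  }
  p <- stats::t.test(drugRbfs, controlRbfs, var.equal = FALSE)$p.value
  list(p_value = p, significant = is.finite(p) && p < alpha)
}

#' Pharmacoscopy scores from per-drug mean RBFs
#'
#' Normalises mean RBFs into pharmacoscopy scores via
#' (1 - RBF) / max(1 - RBF), the max taken over drugs within one
#' patient x marker. A score of 1 marks the strongest on-target ex vivo
#' response, 0 no effect, and negative scores ex vivo chemoresistance.
#' When no drug beats the control (max(1 - RBF) <= 0, within tolerance) all
#' scores are set to 0 with a warning, since the normalisation is undefined.
#'
#' @param rbfMeans named numeric vector of per-drug mean RBFs
#' @return named numeric vector of pharmacoscopy scores
#' @examples
#' pcyScores(c(A = 0.6, B = 1.0, C = 1.4))  # 1, 0, -1
#' @export
pcyScores <- function(rbfMeans) {
  stopifnot(length(rbfMeans) >= 1)
  ok <- is.finite(rbfMeans)
  mx <- max(1 - rbfMeans[ok], na.rm = TRUE)
  if (!is.finite(mx) || mx <= 1e-9) {
    warning("no drug beats control (max(1 - RBF) <= 0); all pharmacoscopy scores set to 0")
    out <- ifelse(ok, 0, NA_real_)
    names(out) <- names(rbfMeans)
    return(out)
  }
  (1 - rbfMeans) / mx
}

#' Rank drugs by mean RBF
#'
#' Ascending mean RBF (strongest on-target depletion first); ties broken
#' lexicographically by drug name so reports are deterministic.
#'
#' @param rows data.frame with columns \code{drug} and \code{rbf_mean}
#' @return the same data.frame ordered by rank, with a \code{rank} column
#' @export
rankDrugs <- function(rows) {
  ord <- order(rows$rbf_mean, rows$drug)
  out <- rows[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Score a full screen into a per-drug response table
#'
#' Runs the scoring engine over every patient x marker in a screen: per-well
#' RBFs normalised to DMSO controls, replicate-then-concentration averaging
#' per drug, Welch t-test significance against controls, ascending-RBF drug
#' ranks, and pharmacoscopy scores.
#'
#' @param screen a [WellScreen-class]
#' @param alpha significance level for the per-drug t-test
#' @param adjust p-value adjustment method (\code{"none"} by default;
#'   \code{"BH"} for Benjamini-Hochberg within each patient x marker)
#' @return data.frame with one row per patient x marker x drug:
#'   \code{patient_id}, \code{marker}, \code{drug}, \code{rbf_mean},
#'   \code{rbf_per_replicate} (list column), \code{p_value},
#'   \code{significant}, \code{rank}, \code{pcy_score}
#' @export
scoreScreen <- function(screen, alpha = 0.05, adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  w <- screen@wells
  out <- list()
  for (p in unique(w$patient_id)) {
    for (m in unique(w$marker[w$patient_id == p])) {
      sub <- w[w$patient_id == p & w$marker == m, , drop = FALSE]
      ctl <- sub[sub$drug == CONTROL_DRUG, , drop = FALSE]
      ctlFrac <- viableFraction(ctl$n_viable_marker_pos, ctl$n_viable_marker_neg)
      ctlMean <- mean(ctlFrac, na.rm = TRUE)
      ctlRbfs <- ctlFrac / ctlMean
      drugs <- setdiff(unique(sub$drug), CONTROL_DRUG)
      if (!length(drugs)) next
      rbfs <- lapply(drugs, function(d) computeRBF(screen, p, m, d))
      rows <- mapply(function(d, r) {
        sig <- drugSignificance(r$rbf_per_replicate, ctlRbfs, alpha = alpha)
        data.frame(patient_id = p, marker = m, drug = d,
                   rbf_mean = r$rbf_mean, p_value = sig$p_value,
                   significant = sig$significant, stringsAsFactors = FALSE)
      }, drugs, rbfs, SIMPLIFY = FALSE)
      tab <- do.call(rbind, rows)
      tab$rbf_per_replicate <- lapply(rbfs, `[[`, "rbf_per_replicate")
      if (adjust == "BH") {
        tab$p_value <- stats::p.adjust(tab$p_value, method = "BH")
        tab$significant <- !is.na(tab$p_value) & tab$p_value < alpha
      }
      tab <- rankDrugs(tab)
      sc <- pcyScores(stats::setNames(tab$rbf_mean, tab$drug))
      tab$pcy_score <- as.numeric(sc[tab$drug])
      out[[length(out) + 1L]] <- tab
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Write a per-patient drug-response report
#'
#' @param scores output of [scoreScreen()]
#' @param path TSV output path
#' @param capDisplay also include a display column with RBF capped at 1.2
#'   (reporting convention; the raw values are never capped)
#' @return invisibly, the written data.frame
#' @export
writeResponseTable <- function(scores, path, capDisplay = TRUE) {
  out <- scores[, c("patient_id", "marker", "drug", "rbf_mean", "p_value",
                    "significant", "rank", "pcy_score")]
  if (capDisplay) out$rbf_display <- pmin(out$rbf_mean, 1.2)
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(out)
}
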