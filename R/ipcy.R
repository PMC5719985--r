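#' Integrated pharmacoscopy (i-PCY) score
#'
#' Treatment regimens usually combine several drugs and screens measure
#' several blast markers per patient; the i-PCY score integrates both by
#' summing the pharmacoscopy scores of the administered drugs over all
#' measured markers. Regimens of on-target drugs yield positive i-PCY; drugs
#' to which ex vivo chemoresistance was measured pull it negative.
#'
#' @param scoreTable data.frame with columns \code{drug}, \code{marker},
#'   \code{pcy_score} for one patient (e.g. a patient's rows from
#'   [scoreScreen()])
#' @param administered character, the drugs in the patient's regimen; every
#'   administered drug must be present in the table for every marker
#' @param patientId optional identifier carried into the result
#' @return list with \code{patient_id}, \code{administered_drugs},
#'   \code{markers}, \code{i_pcy}, and \code{component_scores} (drug x marker
#'   matrix)
#' @examples
#' tab <- data.frame(drug = rep(c("A", "B"), each = 2),
#'                   marker = rep(c("CD34", "CD117"), 2),
#'                   pcy_score = c(1, 0.5, 0.2, -0.2))
#' integrateIPCY(tab, c("A", "B"))$i_pcy  # 1.5
#' @export
integrateIPCY <- function(scoreTable, administered, patientId = NA_character_) {
  markers <- unique(scoreTable$marker)
  key <- paste(scoreTable$drug, scoreTable$marker, sep = "\r")
  want <- expand.grid(drug = administered, marker = markers,
                      stringsAsFactors = FALSE)
  wantKey <- paste(want$drug, want$marker, sep = "\r")
  missing <- wantKey[!wantKey %in% key]
  if (length(missing))
    stop(sprintf("missing drug x marker combination(s): %s",
                 paste(gsub("\r", " x ", missing), collapse = ", ")))
  comp <- matrix(NA_real_, length(administered), length(markers),
                 dimnames = list(administered, markers))
  for (i in seq_along(wantKey)) {
    v <- scoreTable$pcy_score[match(wantKey[i], key)]
    comp[want$drug[i], want$marker[i]] <- v
  }
  list(patient_id = patientId, administered_drugs = administered,
       markers = markers, i_pcy = sum(comp), component_scores = comp)
}

#' Fraction of tested drugs showing ex vivo chemoresistance
#'
#' A drug is called ex vivo resistant when its pharmacoscopy score falls below
#' a threshold (default -0.1; -0.2/-0.3/-0.4 are the usual alternates).
#'
#' @param scores numeric pharmacoscopy scores, one per tested drug
#' @param threshold resistance threshold (scores strictly below count)
#' @return fraction in [0, 1]
#' @examples
#' chemoresistanceFraction(c(-0.5, 0, 0.5, 1))  # 0.25
#' @export
chemoresistanceFraction <- function(scores, threshold = -0.1) {
  scores <- scores[is.finite(scores)]
  if (!length(scores)) return(NA_real_)
  mean(scores < threshold)
}

#' Hierarchical clustering of drug-response profiles
#'
#' Agglomerative clustering with average linkage on 1 - Pearson correlation
#' distance, with missing values pairwise-masked. Clusters both the drug
#' columns and the profile rows (patient x marker); drugs of a shared mode of
#' action, having correlated response columns, co-cluster.
#'
#' @param scoreMatrix numeric matrix, profiles (rows) x drugs (columns) of
#'   pharmacoscopy scores; NAs allowed
#' @return list with \code{drugs} and \code{profiles}, each either an
#'   \code{hclust} object (with a deterministic leaf \code{order}) or NULL
#'   when that dimension has fewer than 2 members, plus \code{drug_order} and
#'   \code{profile_order}
#' @export
clusterProfiles <- function(scoreMatrix) {
  scoreMatrix <- as.matrix(scoreMatrix)
  clusterDim <- function(m) {
    if (nrow(m) < 2) return(NULL)
    cc <- suppressWarnings(stats::cor(t(m), use = "pairwise.complete.obs"))
    cc[!is.finite(cc)] <- 0
    d <- stats::as.dist(1 - cc)
    stats::hclust(d, method = "average")
  }
  hd <- clusterDim(t(scoreMatrix))
  hp <- clusterDim(scoreMatrix)
  list(drugs = hd, profiles = hp,
       drug_order = if (is.null(hd)) seq_len(ncol(scoreMatrix)) else hd$order,
       profile_order = if (is.null(hp)) seq_len(nrow(scoreMatrix)) else hp$order)
}
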