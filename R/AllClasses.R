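#' @import methods
NULL

WELL_TABLE_COLUMNS <- c("patient_id", "plate_id", "well", "drug",
                        "concentration_um", "replicate", "marker",
                        "n_viable_marker_pos", "n_viable_marker_neg",
                        "n_total_cells")

CONTROL_DRUG <- "DMSO"

#' WellScreen: per-well single-cell derived counts for an ex vivo drug screen
#'
#' Container for the long-format well table of an image-based drug screen:
#' one row per well x marker, holding counts of viable marker-positive and
#' marker-negative cells plus plate/drug/concentration/replicate annotations.
#' Wells with \code{drug == "DMSO"} at concentration 0 are the vehicle
#' controls that define the normalisation baseline for relative blast
#' fractions.
#'
#' @slot wells data.frame with columns \code{patient_id}, \code{plate_id},
#'   \code{well} (384-well coordinate, e.g. "A1".."P24"), \code{drug},
#'   \code{concentration_um}, \code{replicate}, \code{marker},
#'   \code{n_viable_marker_pos}, \code{n_viable_marker_neg},
#'   \code{n_total_cells}.
#'
#' @seealso [readWellTable()], [scoreScreen()]
#' @export
setClass("WellScreen", representation(wells = "data.frame"))

validWellScreen <- function(object) {
  w <- object@wells
  msg <- character()
  missing <- setdiff(WELL_TABLE_COLUMNS, names(w))
  if (length(missing))
    return(sprintf("missing column(s): %s", paste(missing, collapse = ", ")))
  counts <- c("n_viable_marker_pos", "n_viable_marker_neg", "n_total_cells")
  for (col in counts) {
    bad <- which(!is.finite(w[[col]]) | w[[col]] < 0)
    if (length(bad))
      msg <- c(msg, sprintf("negative or non-finite %s at row %d", col, bad[1]))
  }
  if (!length(msg)) {
    over <- which(w$n_viable_marker_pos + w$n_viable_marker_neg >
                    w$n_total_cells)
    if (length(over))
      msg <- c(msg, sprintf(
        "viable pos+neg exceeds n_total_cells at row %d", over[1]))
    badwell <- which(!isValidWell384(w$well))
    if (length(badwell))
      msg <- c(msg, sprintf("well '%s' (row %d) outside the 16x24 grid",
                            w$well[badwell[1]], badwell[1]))
    ctlconc <- which(w$drug == CONTROL_DRUG & w$concentration_um != 0)
    if (length(ctlconc))
      msg <- c(msg, sprintf("DMSO control well with nonzero concentration at row %d",
                            ctlconc[1]))
    dup <- duplicated(w[, c("patient_id", "plate_id", "well", "marker")])
    if (any(dup))
      msg <- c(msg, sprintf("duplicate (patient, plate, well, marker) at row %d",
                            which(dup)[1]))
    neg <- which(w$replicate < 1)
    if (length(neg))
      msg <- c(msg, sprintf("non-positive replicate at row %d", neg[1]))
  }
  if (length(msg)) msg else TRUE
}
setValidity("WellScreen", validWellScreen)

#' Parse and validate 384-well coordinates
#'
#' @param well character vector like "A1", "P24".
#' @return logical vector, TRUE where the coordinate lies in the 16x24 grid.
#' @keywords internal
isValidWell384 <- function(well) {
  m <- regmatches(well, regexec("^([A-Pa-p])([0-9]{1,2})$", as.character(well)))
  vapply(m, function(p) {
    if (length(p) != 3) return(FALSE)
    col <- as.integer(p[3])
    col >= 1 && col <= 24
  }, logical(1))
}

#' DrugMatrixCohort: per-patient drug-matrix response profiles with labels
#'
#' Holds, for a cohort of patients screened through the same drug-concentration
#' combination matrix, the DMSO-normalised replicate values at every matrix
#' point for up to three cellular readouts: the relative blast fraction
#' (\code{"rbf"}), the DMSO-relative total cell count (\code{"total_cells"})
#' and the DMSO-relative total blast count (\code{"total_blasts"}). Each assay
#' is an array of dimension patients x points x replicates.
#'
#' @slot assays named list of 3-d numeric arrays (patients x matrix points x
#'   replicates), all with identical dimensions.
#' @slot labels factor with levels \code{complete_remission},
#'   \code{non_responder}, one per patient.
#' @slot patientIds character vector of patient identifiers.
#'
#' @seealso [simulateAmlCohort()], [leaveKOutCV()]
#' @export
setClass("DrugMatrixCohort", representation(
  assays = "list", labels = "factor", patientIds = "character"))

setValidity("DrugMatrixCohort", function(object) {
  if (!length(object@assays)) return("no assays")
  dims <- lapply(object@assays, dim)
  if (any(vapply(dims, length, 1L) != 3L))
    return("assays must be 3-d arrays (patients x points x replicates)")
  if (length(unique(vapply(dims, paste, "", collapse = "x"))) != 1L)
    return("assay dimensions differ")
  n <- dims[[1]][1]
  if (length(object@labels) != n || length(object@patientIds) != n)
    return("labels/patientIds length must equal the number of patients")
  if (!all(levels(object@labels) %in% c("complete_remission", "non_responder")))
    return("labels must be complete_remission / non_responder")
  TRUE
})

#' HyperplaneModel: per-matrix-point separating surface with AUROC weights
#'
#' An axis-aligned decision surface over the drug matrix: for every matrix
#' point a threshold, an orientation saying which side is responder-like
#' (+1: below the threshold), and a weight equal to the AUROC of that point
#' on the training cohort (re-oriented so weights are always >= 0.5).
#' \code{cut} is the training-derived cut on integrated response scores used
#' to classify held-out patients.
#'
#' @slot threshold numeric, per-point thresholds.
#' @slot orientation integer, +1 (below = responder-like) or -1.
#' @slot weight numeric in [0, 1], per-point AUROC.
#' @slot readout character, which assay the model was fitted on.
#' @slot cut numeric(1), classification cut on integrated scores.
#'
#' @seealso [fitHyperplane()], [integratedResponseScore()]
#' @export
setClass("HyperplaneModel", representation(
  threshold = "numeric", orientation = "integer", weight = "numeric",
  readout = "character", cut = "numeric"))

setValidity("HyperplaneModel", function(object) {
  n <- length(object@threshold)
  if (length(object@orientation) != n || length(object@weight) != n)
    return("threshold/orientation/weight lengths differ")
  if (any(!is.finite(object@threshold))) return("non-finite threshold")
  if (any(object@weight < 0 | object@weight > 1)) return("weight outside [0,1]")
  if (any(!object@orientation %in% c(-1L, 1L))) return("orientation must be +/-1")
  TRUE
})

CLINICAL_RESPONSES <- c("PD", "SD", "PR", "CR")

#' ClinicalCohort: per-patient clinical outcome records
#'
#' Mirrors a clinical characteristics table: diagnosis, best overall response
#' (CR/PR/SD/PD, with the ordinal coding 1=PD, 2=SD, 3=PR, 4=CR), PFS in
#' weeks, and whether the response was ongoing at the censoring date (ongoing
#' responses are right-censored in survival analyses). Optional columns carry
#' the most recent prior regimen's response and PFS, and the patient's
#' integrated pharmacoscopy (i-PCY) score.
#'
#' @slot records data.frame with at least \code{patient_id},
#'   \code{overall_response}, \code{pfs_weeks}, \code{ongoing}; optionally
#'   \code{diagnosis}, \code{prior_response}, \code{prior_pfs_weeks},
#'   \code{i_pcy}, \code{prior_lines}.
#'
#' @seealso [readClinicalTable()], [guidedCohort()], [kmCurve()]
#' @export
setClass("ClinicalCohort", representation(records = "data.frame"))

setValidity("ClinicalCohort", function(object) {
  r <- object@records
  need <- c("patient_id", "overall_response", "pfs_weeks", "ongoing")
  missing <- setdiff(need, names(r))
  if (length(missing))
    return(sprintf("missing column(s): %s", paste(missing, collapse = ", ")))
  if (!all(r$overall_response %in% CLINICAL_RESPONSES))
    return("overall_response must be one of PD, SD, PR, CR")
  if (any(!is.finite(r$pfs_weeks) | r$pfs_weeks < 0))
    return("pfs_weeks must be non-negative")
  if (!is.logical(r$ongoing)) return("ongoing must be logical")
  TRUE
})

#' @describeIn WellScreen number of well x marker rows
#' @param x,object a \code{WellScreen}
#' @export
setMethod("length", "WellScreen", function(x) nrow(x@wells))

setMethod("show", "WellScreen", function(object) {
  w <- object@wells
  cat(sprintf(
    "WellScreen: %d well x marker rows, %d patient(s), %d drug(s), %d marker(s)\n",
    nrow(w), length(unique(w$patient_id)),
    length(setdiff(unique(w$drug), CONTROL_DRUG)),
    length(unique(w$marker))))
  cat(sprintf("  control wells (%s): %d\n", CONTROL_DRUG,
              sum(w$drug == CONTROL_DRUG & !duplicated(
                w[, c("patient_id", "plate_id", "well")]))))
})

setMethod("show", "DrugMatrixCohort", function(object) {
  d <- dim(object@assays[[1]])
  cat(sprintf(
    "DrugMatrixCohort: %d patients x %d matrix points x %d replicates\n",
    d[1], d[2], d[3]))
  cat(sprintf("  readouts: %s\n", paste(names(object@assays), collapse = ", ")))
  cat(sprintf("  labels: %s\n",
              paste(sprintf("%s=%d", levels(object@labels),
                            tabulate(object@labels, length(levels(object@labels)))),
                    collapse = ", ")))
})

setMethod("show", "HyperplaneModel", function(object) {
  cat(sprintf(
    "HyperplaneModel (%s): %d matrix points, mean AUROC weight %.3f, cut %.3f\n",
    object@readout, length(object@threshold), mean(object@weight), object@cut))
})

setMethod("show", "ClinicalCohort", function(object) {
  r <- object@records
  cat(sprintf("ClinicalCohort: %d patients, %d responders (CR/PR), %d ongoing\n",
              nrow(r), sum(r$overall_response %in% c("CR", "PR")),
              sum(r$ongoing)))
})

#' @describeIn WellScreen the well table
#' @export
wells <- function(x) x@wells

#' @describeIn ClinicalCohort the clinical records table
#' @param x a \code{ClinicalCohort}
#' @export
clinicalRecords <- function(x) x@records

#' Accessors for DrugMatrixCohort
#'
#' @param x a \code{DrugMatrixCohort}
#' @param readout one of \code{"rbf"}, \code{"total_cells"},
#'   \code{"total_blasts"}
#' @return \code{assayArray}: the patients x points x replicates array;
#'   \code{patientMeans}: patients x points matrix of replicate means;
#'   \code{cohortLabels}: the label factor.
#' @export
assayArray <- function(x, readout = "rbf") {
  if (!readout %in% names(x@assays))
    stop(sprintf("unknown readout '%s'; available: %s", readout,
                 paste(names(x@assays), collapse = ", ")))
  x@assays[[readout]]
}

#' @rdname assayArray
#' @export
patientMeans <- function(x, readout = "rbf") {
  a <- assayArray(x, readout)
  apply(a, c(1, 2), mean, na.rm = TRUE)
}

#' @rdname assayArray
#' @export
cohortLabels <- function(x) x@labels
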