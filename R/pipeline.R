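configHash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                              force = TRUE), tmp)
  unname(tools::md5sum(tmp))
}

writeManifest <- function(dir, command, config, inputs = list(),
                          outputs = list()) {
  man <- list(command = command,
              package_version = as.character(utils::packageVersion("pharmacoscopy")),
              config = config, config_hash = configHash(config),
              inputs = inputs, outputs = outputs)
  jsonlite::write_json(man, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(man)
}

#' Simulate a screen dataset to disk
#'
#' Writes a well-count CSV in the [readWellTable()] schema, the truth table
#' (TSV) of expected per-drug RBFs, and a manifest (config, config hash,
#' package version) into a dataset directory. Re-running with the same config
#' and seed reproduces the files byte-identically.
#'
#' @param dir output directory (created)
#' @param config a [screenSimConfig()] or preset name for
#'   [presetScreenConfig()]
#' @param patientId,marker annotations for the generated records
#' @return invisibly, the dataset directory
#' @export
runSimulate <- function(dir, config = "prospective139x2x5",
                        patientId = "SIM1", marker = "CD34") {
  if (is.character(config)) config <- presetScreenConfig(config)
  stopifnot(inherits(config, "screenSimConfig"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulateScreen(config, patientId = patientId, marker = marker)
  wellsCsv <- file.path(dir, "wells.csv")
  utils::write.csv(wells(sim$screen), wellsCsv, row.names = FALSE)
  truthTsv <- file.path(dir, "truth.tsv")
  utils::write.table(sim$truth, truthTsv, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  writeManifest(dir, "simulate", unclass(config),
                outputs = list(wells = "wells.csv", truth = "truth.tsv"))
  invisible(dir)
}

#' Score a screen dataset into a drug-response report
#'
#' Reads the dataset's well table, runs the scoring engine, and writes the
#' ranked per-patient drug-response TSV (with a display column capping RBF at
#' 1.2 alongside the raw values) plus a manifest.
#'
#' @param dir dataset directory containing \code{wells.csv} (from
#'   [runSimulate()]) or a path to a well CSV
#' @param out output directory (defaults to \code{dir})
#' @param alpha significance level
#' @return invisibly, the scored data.frame
#' @export
runScore <- function(dir, out = NULL, alpha = 0.05) {
  csv <- if (dir.exists(dir)) file.path(dir, "wells.csv") else dir
  if (!file.exists(csv)) stop(sprintf("no well table at %s", csv))
  if (is.null(out)) out <- dirname(csv)
  screen <- readWellTable(csv)
  scores <- scoreScreen(screen, alpha = alpha)
  writeResponseTable(scores, file.path(out, "drug_response.tsv"))
  writeManifest(out, "score", list(wells = csv, alpha = alpha),
                inputs = list(wells = csv),
                outputs = list(response = "drug_response.tsv"))
  invisible(scores)
}

#' Cross-validated response classification of a simulated AML cohort
#'
#' Simulates (or accepts) a two-class drug-matrix cohort, runs leave-k-out
#' cross-validation on the chosen readout, and writes per-run accuracies
#' (CSV), the vertically averaged ROC curve (TSV) and a summary JSON.
#'
#' @param dir output directory
#' @param cohort a [DrugMatrixCohort-class]; when NULL one is simulated from
#'   \code{config}
#' @param config a [cohortSimConfig()] used when \code{cohort} is NULL
#' @param readout assay to classify on
#' @param k_per_class held-out patients per class (k = 2 on the 10+10 design
#'   gives 2025 runs)
#' @return invisibly, the [leaveKOutCV()] result
#' @export
runAmlCV <- function(dir, cohort = NULL, config = cohortSimConfig(),
                     readout = "rbf", k_per_class = 2) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(cohort)) cohort <- simulateAmlCohort(config)
  cv <- leaveKOutCV(cohort, readout = readout, k_per_class = k_per_class)
  utils::write.csv(data.frame(run = seq_along(cv$accuracies),
                              accuracy = cv$accuracies),
                   file.path(dir, "cv_runs.csv"), row.names = FALSE)
  utils::write.table(cv$roc, file.path(dir, "roc.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(n_runs = cv$n_runs,
                            mean_accuracy = cv$mean_accuracy,
                            auroc = cv$auroc),
                       file.path(dir, "cv_summary.json"), auto_unbox = TRUE,
                       digits = NA)
  writeManifest(dir, "aml-cv",
                list(readout = readout, k_per_class = k_per_class,
                     config = if (is.null(cohort)) unclass(config) else NULL),
                outputs = list(runs = "cv_runs.csv", roc = "roc.tsv",
                               summary = "cv_summary.json"))
  invisible(cv)
}

#' Clinical endpoint report for an outcome table
#'
#' Reads a clinical CSV, computes the endpoint summary (responders, PD count,
#' KM median with ongoing responses censored, odds ratio and McNemar test
#' against the prior regimen when margins are known) and writes an endpoint
#' JSON plus the KM step function as TSV.
#'
#' @param path clinical CSV ([readClinicalTable()] schema) or a
#'   [ClinicalCohort-class]
#' @param dir output directory
#' @param respondersPrior,discordantPriorOnly prior-regimen margins passed to
#'   [outcomeSummary()]
#' @return invisibly, the endpoint summary list
#' @export
runOutcomes <- function(path, dir, respondersPrior = NULL,
                        discordantPriorOnly = 0) {
  cohort <- if (is(path, "ClinicalCohort")) path else readClinicalTable(path)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  s <- outcomeSummary(cohort, respondersPrior = respondersPrior,
                      discordantPriorOnly = discordantPriorOnly)
  r <- clinicalRecords(cohort)
  km <- kmCurve(r$pfs_weeks, !r$ongoing)
  utils::write.table(data.frame(time = km$time, surv = km$surv,
                                n_risk = km$n_risk, n_event = km$n_event),
                     file.path(dir, "km.tsv"), sep = "\t", row.names = FALSE,
                     quote = FALSE)
  out <- s
  out$km_median <- if (is.na(out$km_median)) "undefined" else out$km_median
  jsonlite::write_json(out, file.path(dir, "endpoints.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  writeManifest(dir, "outcomes",
                list(respondersPrior = respondersPrior,
                     discordantPriorOnly = discordantPriorOnly),
                outputs = list(endpoints = "endpoints.json", km = "km.tsv"))
  invisible(s)
}
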