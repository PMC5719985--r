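# Programmatic fixtures shared across test files.

tinyWellTable <- function() {
  data.frame(
    patient_id = "P1", plate_id = "plate1",
    well = c("A1", "A2", "B1", "B2", "B3"),
    drug = c("DMSO", "DMSO", "drugX", "drugX", "drugY"),
    concentration_um = c(0, 0, 1, 1, 1),
    replicate = c(1, 2, 1, 2, 1), marker = "CD34",
    n_viable_marker_pos = c(40, 40, 20, 22, 41),
    n_viable_marker_neg = c(60, 60, 60, 78, 59),
    n_total_cells = c(110, 110, 105, 105, 105),
    stringsAsFactors = FALSE)
}

writeTempCsv <- function(df) {
  path <- tempfile(fileext = ".csv")
  write.csv(df, path, row.names = FALSE)
  path
}

# A random valid one-patient well table with known structure.
randomWellTable <- function(seed, nDrugs = 3, nCtl = 4, nReps = 3) {
  set.seed(seed)
  drugs <- paste0("d", seq_len(nDrugs))
  rows <- expand.grid(drug = drugs, replicate = seq_len(nReps),
                      stringsAsFactors = FALSE)
  rows <- rbind(data.frame(drug = "DMSO", replicate = seq_len(nCtl)), rows)
  n <- nrow(rows)
  tot <- sample(200:800, n, replace = TRUE)
  pos <- rbinom(n, tot, runif(1, 0.3, 0.8))
  data.frame(
    patient_id = "P1", plate_id = "plate1",
    well = paste0(rep(LETTERS[1:16], each = 24), 1:24)[seq_len(n)],
    drug = rows$drug,
    concentration_um = ifelse(rows$drug == "DMSO", 0,
                              ifelse(rows$replicate > nReps / 2, 10, 1)),
    replicate = rows$replicate, marker = "CD34",
    n_viable_marker_pos = pos, n_viable_marker_neg = tot - pos,
    n_total_cells = tot + sample(0:50, n, replace = TRUE),
    stringsAsFactors = FALSE)
}

# Small two-class matrix cohort with perfectly separated classes.
separatedCohort <- function(nPerClass = 4, nPts = 10, nReps = 2, gap = 0.5,
                            seed = 1) {
  set.seed(seed)
  n <- 2 * nPerClass
  a <- array(NA_real_, dim = c(n, nPts, nReps))
  for (i in seq_len(n)) {
    base <- if (i <= nPerClass) 1 - gap else 1
    a[i, , ] <- base + rnorm(nPts * nReps, 0, 0.02)
  }
  new("DrugMatrixCohort",
      assays = list(rbf = a),
      labels = factor(rep(c("complete_remission", "non_responder"),
                          each = nPerClass),
                      levels = c("complete_remission", "non_responder")),
      patientIds = sprintf("S%02d", seq_len(n)))
}
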