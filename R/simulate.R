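#' Configuration for a simulated single-patient drug screen
#'
#' Describes the geometry and noise model of a simulated 384-well ex vivo
#' screen. Initial per-well cell counts are lognormal around
#' \code{cells_per_well} (coefficient of variation \code{seeding_cv},
#' emulating seeding-density variation between wells); the marker-positive
#' (blast) count is beta-binomial around \code{blast_fraction} with a single
#' \code{overdispersion} parameter (0 = plain binomial); drug exposure then
#' kills marker-positive cells with probability \code{on_target[drug]} and
#' marker-negative cells with \code{off_target[drug]}, each scaled by a
#' Hill-type dose factor c / (c + EC50) with EC50 at the geometric mid of the
#' tested concentration range (\code{ec50 = 0} disables dose scaling).
#'
#' @param n_drugs number of drugs
#' @param concentrations tested concentrations, uM
#' @param n_replicates technical replicates per concentration; scalar or a
#'   vector with one entry per concentration
#' @param n_control_wells DMSO wells per 384-well plate
#' @param cells_per_well mean initial cells per well
#' @param blast_fraction expected marker-positive fraction
#' @param on_target,off_target kill probabilities at saturating dose; scalar
#'   (recycled) or length \code{n_drugs}
#' @param overdispersion beta-binomial overdispersion in [0, 1)
#' @param seeding_cv lognormal CV of the per-well initial cell count
#' @param ec50 Hill EC50; NULL = geometric mid of nonzero concentrations,
#'   0 = no dose scaling
#' @param seed integer RNG seed
#' @return a \code{screenSimConfig} list
#' @export
screenSimConfig <- function(n_drugs = 139, concentrations = c(1, 10),
                            n_replicates = c(3, 2), n_control_wells = 16,
                            cells_per_well = 2000, blast_fraction = 0.6,
                            on_target = 0, off_target = 0,
                            overdispersion = 0.002, seeding_cv = 0.25,
                            ec50 = NULL, seed = 1L) {
  nr <- if (length(n_replicates) == 1)
    rep(n_replicates, length(concentrations)) else n_replicates
  stopifnot(length(nr) == length(concentrations),
            all(nr >= 1), n_drugs >= 1,
            blast_fraction > 0, blast_fraction < 1,
            overdispersion >= 0, overdispersion < 1)
  on_target <- rep_len(on_target, n_drugs)
  off_target <- rep_len(off_target, n_drugs)
  if (any(on_target < 0 | on_target > 1 | off_target < 0 | off_target > 1))
    stop("kill probabilities must lie in [0, 1]")
  if (is.null(ec50)) {
    cc <- concentrations[concentrations > 0]
    ec50 <- if (length(cc)) sqrt(min(cc) * max(cc)) else 0
  }
  structure(list(n_drugs = n_drugs, concentrations = concentrations,
                 n_replicates = nr, n_control_wells = n_control_wells,
                 cells_per_well = cells_per_well,
                 blast_fraction = blast_fraction,
                 on_target = on_target, off_target = off_target,
                 overdispersion = overdispersion, seeding_cv = seeding_cv,
                 ec50 = ec50, seed = as.integer(seed)),
            class = "screenSimConfig")
}

#' Preset screen geometries
#'
#' \code{"prospective139x2x5"}: 139 drugs at two concentrations with five
#' technical replicates per drug in total (3 + 2 across the two
#' concentrations), as used for most prospectively screened patients.
#' \code{"aml_matrix_25x5x4"}: the three-drug combination matrix of first-line
#' AML therapy (cytarabine, daunorubicin, etoposide), 125 unique
#' drug-concentration combinations in four technical repeats.
#'
#' @param name preset name
#' @param ... overrides passed to [screenSimConfig()]
#' @return a \code{screenSimConfig}
#' @export
presetScreenConfig <- function(name = c("prospective139x2x5",
                                        "aml_matrix_25x5x4"), ...) {
  name <- match.arg(name)
  if (name == "prospective139x2x5")
    screenSimConfig(n_drugs = 139, concentrations = c(1, 10),
                    n_replicates = c(3, 2), ...)
  else
    screenSimConfig(n_drugs = 125, concentrations = 1, n_replicates = 4, ...)
}

hillFactor <- function(conc, ec50) {
  if (ec50 <= 0) as.numeric(conc > 0) else conc / (conc + ec50)
}

rBetaBinom <- function(n, size, prob, rho) {
  if (rho <= 0) return(stats::rbinom(n, size, prob))
  shape <- (1 / rho) - 1
  p <- stats::rbeta(n, prob * shape, (1 - prob) * shape)
  stats::rbinom(n, size, p)
}

wellIds384 <- function(n) {
  rows <- LETTERS[1:16]
  ids <- as.vector(t(outer(rows, 1:24, paste0)))
  perPlate <- 384
  plate <- (seq_len(n) - 1) %/% perPlate + 1
  data.frame(plate_id = sprintf("plate%d", plate),
             well = ids[((seq_len(n) - 1) %% perPlate) + 1],
             stringsAsFactors = FALSE)
}

sampleWellCounts <- function(n, cfg) {
  sigma <- sqrt(log(1 + cfg$seeding_cv^2))
  mu <- log(cfg$cells_per_well) - sigma^2 / 2
  pmax(1L, as.integer(round(stats::rlnorm(n, mu, sigma))))
}

#' Simulate a single-patient drug screen at the well-count level
#'
#' Draws per-well initial counts, splits them into marker-positive and
#' marker-negative populations, applies dose-scaled binomial survival under
#' each drug, and returns both a [WellScreen-class] (the generator writes the
#' same long-format table the scoring engine reads) and a truth table of
#' expected relative blast fractions per drug.
#'
#' The closed-form expectation used in the truth table: with blast fraction f
#' and kill probabilities k_on, k_off at a given dose, the expected treated
#' marker-positive fraction is (1-k_on) f / ((1-k_on) f + (1-k_off)(1-f)),
#' and the expected RBF divides this by f (the expected control fraction).
#' Proportional killing (k_on = k_off) therefore gives expected RBF 1 at any
#' dose.
#'
#' @param config a [screenSimConfig()]
#' @param patientId patient identifier for the generated records
#' @param marker marker name for the generated records
#' @return list with \code{screen} (a \code{WellScreen}) and \code{truth}
#'   (data.frame: drug, concentration_um, kill_on, kill_off, expected_rbf,
#'   plus per-drug means in \code{attr(truth, "per_drug")})
#' @export
simulateScreen <- function(config, patientId = "SIM1", marker = "CD34") {
  stopifnot(inherits(config, "screenSimConfig"))
  set.seed(config$seed)
  f <- config$blast_fraction
  drugs <- sprintf("drug%03d", seq_len(config$n_drugs))
  grid <- do.call(rbind, lapply(seq_along(config$concentrations), function(i)
    data.frame(conc = config$concentrations[i],
               replicate = seq_len(config$n_replicates[i]))))
  lay <- expand.grid(di = seq_len(config$n_drugs), gi = seq_len(nrow(grid)))
  dw <- data.frame(drug = drugs[lay$di],
                   concentration_um = grid$conc[lay$gi],
                   replicate = grid$replicate[lay$gi],
                   kon = config$on_target[lay$di],
                   koff = config$off_target[lay$di],
                   stringsAsFactors = FALSE)
  dw <- dw[order(dw$drug, dw$concentration_um, dw$replicate), ]
  nDrugWells <- nrow(dw)
  nPlates <- ceiling(nDrugWells / (384 - config$n_control_wells))
  nCtl <- nPlates * config$n_control_wells
  all <- rbind(
    data.frame(drug = CONTROL_DRUG, concentration_um = 0,
               replicate = seq_len(nCtl), kon = 0, koff = 0,
               stringsAsFactors = FALSE),
    dw)
  coords <- wellIds384(nrow(all))
  n <- nrow(all)
  hf <- hillFactor(all$concentration_um, config$ec50)
  killOn <- all$kon * hf
  killOff <- all$koff * hf
  if (any(killOn < 0 | killOn > 1 | killOff < 0 | killOff > 1))
    stop("config error: kill probability outside [0, 1] after dose scaling")
  N <- sampleWellCounts(n, config)
  pos0 <- rBetaBinom(n, N, f, config$overdispersion)
  neg0 <- N - pos0
  pos <- stats::rbinom(n, pos0, 1 - killOn)
  neg <- stats::rbinom(n, neg0, 1 - killOff)
  wellsDf <- data.frame(
    patient_id = patientId, plate_id = coords$plate_id, well = coords$well,
    drug = all$drug, concentration_um = all$concentration_um,
    replicate = all$replicate, marker = marker,
    n_viable_marker_pos = pos, n_viable_marker_neg = neg,
    n_total_cells = N, stringsAsFactors = FALSE)
  truth <- unique(data.frame(
    drug = all$drug, concentration_um = all$concentration_um,
    kill_on = killOn, kill_off = killOff, stringsAsFactors = FALSE))
  truth <- truth[truth$drug != CONTROL_DRUG, ]
  truth$expected_rbf <- expectedRBF(f, truth$kill_on, truth$kill_off)
  perDrug <- stats::aggregate(expected_rbf ~ drug, truth, mean)
  attr(truth, "per_drug") <- perDrug
  rownames(truth) <- NULL
  list(screen = WellScreen(wellsDf), truth = truth)
}

#' Expected relative blast fraction under given kill probabilities
#'
#' @param f blast fraction; \code{kon}, \code{koff}: kill probabilities of the
#'   marker-positive and marker-negative populations at the realised dose.
#' @return expected RBF
#' @export
expectedRBF <- function(f, kon, koff) {
  (1 - kon) / ((1 - kon) * f + (1 - koff) * (1 - f))
}

#' Configuration for a simulated two-class AML cohort
#'
#' @param n_responders,n_nonresponders class sizes (the study design has ten
#'   complete-remission and ten non-responder samples)
#' @param effect_gap mean RBF difference between classes at saturating dose
#'   of an index drug (responders' expected RBF = 1 - effect_gap)
#' @param blast_fraction_range per-patient blast fractions are drawn
#'   uniformly from this interval (clinically 30\% to over 90\%)
#' @param off_target mean non-specific kill probability at saturating dose,
#'   identical in both classes
#' @param off_target_sd patient-level lognormal sd of the non-specific kill
#'   (sample-quality variation between biopsies)
#' @param nonresponder_effect residual on-target kill in non-responders
#' @param kill_sd per-drug lognormal sd on kill probabilities within a
#'   patient
#' @param outlier_responder if TRUE, one responder gets a null ex vivo
#'   response (a complete-remission patient for whom no ex vivo response is
#'   measured)
#' @param n_replicates technical replicates per matrix point
#' @param n_concentrations concentrations per drug in the combination grid
#'   (including 0); three drugs at five concentrations give the 125-point
#'   matrix
#' @param count_drift_sd sd of the per-patient log-scale count drift across
#'   the well sequence (dispensing/settling and imaging drift). The drift is
#'   linear in well order with a random per-patient slope; because control
#'   wells occupy a fixed block, it biases absolute DMSO-relative counts but
#'   cancels in within-well fractions (RBF).
#' @param count_block_sd sd of the per-patient log-scale count offset between
#'   the control block and the drug wells (handling-time and plate-region
#'   bias). Like the drift, it moves every absolute DMSO-relative readout of
#'   a patient coherently and cancels in within-well fractions.
#' @param cells_per_well,n_control_wells,overdispersion,seeding_cv,seed as in
#'   [screenSimConfig()]
#' @return a \code{cohortSimConfig} list
#' @export
cohortSimConfig <- function(n_responders = 10, n_nonresponders = 10,
                            effect_gap = 0.5,
                            blast_fraction_range = c(0.3, 0.95),
                            off_target = 0.2, off_target_sd = 0.5,
                            nonresponder_effect = 0.03,
                            kill_sd = 0.3, count_drift_sd = 0.4,
                            count_block_sd = 0.35,
                            outlier_responder = FALSE,
                            n_replicates = 4, n_concentrations = 5,
                            cells_per_well = 2000, n_control_wells = 16,
                            overdispersion = 0.002, seeding_cv = 0.35,
                            seed = 1L) {
  stopifnot(effect_gap >= 0, effect_gap < 1,
            blast_fraction_range[1] >= 0.3 - 1e-9,
            blast_fraction_range[2] <= 0.95 + 1e-9)
  structure(as.list(environment()), class = "cohortSimConfig")
}

#' Simulate a two-class AML drug-matrix cohort
#'
#' Generates per-patient drug-matrix profiles over a three-drug combination
#' grid (each drug at \code{n_concentrations} doses including 0; 5^3 = 125
#' unique combinations in the default preset), with responders carrying a
#' stronger on-target kill that is monotone in concentration and
#' non-responders near-null effects. All three readouts (relative blast
#' fraction, DMSO-relative total cells, DMSO-relative total blasts) are
#' simulated from the same underlying per-well counts.
#'
#' @param config a [cohortSimConfig()]
#' @return a [DrugMatrixCohort-class]; \code{attr(, "truth")} holds the
#'   per-patient expected RBF matrix and the matrix-point definitions
#' @export
simulateAmlCohort <- function(config) {
  stopifnot(inherits(config, "cohortSimConfig"))
  set.seed(config$seed)
  nR <- config$n_responders; nN <- config$n_nonresponders
  n <- nR + nN
  labels <- factor(rep(c("complete_remission", "non_responder"), c(nR, nN)),
                   levels = c("complete_remission", "non_responder"))
  ids <- sprintf("AML%02d", seq_len(n))
  concs <- seq(0, 1, length.out = config$n_concentrations)
  pts <- expand.grid(c1 = concs, c2 = concs, c3 = concs)
  nPts <- nrow(pts)
  ec50 <- 0.25  # on the unit dose scale of the grid
  hf <- vapply(1:3, function(d) hillFactor(pts[[d]], ec50), numeric(nPts))
  f <- stats::runif(n, config$blast_fraction_range[1],
                    config$blast_fraction_range[2])
  # per-patient saturating on-target kill per drug
  targetRbf <- 1 - config$effect_gap
  killFor <- function(r, fi) pmin(0.98, pmax(0, (1 - r) / (1 - r * fi)))
  nReps <- config$n_replicates
  mkAssay <- function() array(NA_real_, dim = c(n, nPts, nReps))
  assays <- list(rbf = mkAssay(), total_cells = mkAssay(),
                 total_blasts = mkAssay())
  expRbf <- matrix(NA_real_, n, nPts)
  wellCfg <- screenSimConfig(n_drugs = 1, cells_per_well = config$cells_per_well,
                             overdispersion = config$overdispersion,
                             seeding_cv = config$seeding_cv)
  outlierIdx <- if (config$outlier_responder && nR >= 1) 1L else 0L
  for (i in seq_len(n)) {
    isResp <- labels[i] == "complete_remission" && i != outlierIdx
    base <- if (isResp) killFor(targetRbf, f[i]) else config$nonresponder_effect
    kmax <- pmin(0.98, base * stats::rlnorm(3, 0, config$kill_sd))
    # one sample-quality factor per patient, small per-drug variation on top
    qual <- stats::rlnorm(1, 0, config$off_target_sd)
    koffmax <- pmin(0.9, config$off_target * qual *
                      stats::rlnorm(3, 0, config$kill_sd / 2))
    kon <- 1 - apply(1 - sweep(hf, 2, kmax, `*`), 1, prod)
    koff <- 1 - apply(1 - sweep(hf, 2, koffmax, `*`), 1, prod)
    expRbf[i, ] <- expectedRBF(f[i], kon, koff)
    nCtl <- config$n_control_wells
    nWells <- nCtl + nPts * nReps
    cfg <- wellCfg; cfg$blast_fraction <- f[i]; cfg$seeding_cv <- config$seeding_cv
    N <- sampleWellCounts(nWells, cfg)
    # per-patient count drift along the dispensing/imaging sequence: biases
    # absolute counts relative to the control block, cancels in fractions
    slope <- stats::rnorm(1, 0, config$count_drift_sd)
    block <- stats::rnorm(1, 0, config$count_block_sd)
    posSeq <- seq_len(nWells) / nWells
    isCtlWell <- seq_len(nWells) <= nCtl
    drift <- exp(slope * (posSeq - mean(posSeq[isCtlWell])) +
                   block * !isCtlWell)
    N <- pmax(1L, as.integer(round(N * drift)))
    pos0 <- rBetaBinom(nWells, N, f[i], config$overdispersion)
    neg0 <- N - pos0
    killOnW <- c(rep(0, nCtl), rep(kon, each = nReps))
    killOffW <- c(rep(0, nCtl), rep(koff, each = nReps))
    pos <- stats::rbinom(nWells, pos0, 1 - killOnW)
    neg <- stats::rbinom(nWells, neg0, 1 - killOffW)
    ctl <- seq_len(nCtl)
    ctlFrac <- mean(pos[ctl] / (pos[ctl] + neg[ctl]))
    ctlTot <- mean(pos[ctl] + neg[ctl])
    ctlPos <- mean(pos[ctl])
    idx <- matrix(seq_len(nPts * nReps) + nCtl, nrow = nReps)
    frac <- pos / (pos + neg)
    for (j in seq_len(nPts)) {
      w <- idx[, j]
      assays$rbf[i, j, ] <- frac[w] / ctlFrac
      assays$total_cells[i, j, ] <- (pos[w] + neg[w]) / ctlTot
      assays$total_blasts[i, j, ] <- pos[w] / ctlPos
    }
  }
  obj <- new("DrugMatrixCohort", assays = assays, labels = labels,
             patientIds = ids)
  attr(obj, "truth") <- list(expected_rbf = expRbf, points = pts,
                             blast_fraction = f, outlier = outlierIdx)
  obj
}

#' Simulate paired clinical outcome records
#'
#' Draws exponential progression-free survival for a prior regimen and a
#' subsequent (e.g. screen-guided) regimen with a configurable hazard ratio,
#' applies administrative censoring (\code{ongoing = TRUE} at the censoring
#' horizon), and samples ordinal best responses (1=PD .. 4=CR) with
#' probability increasing in a simulated i-PCY score through a
#' proportional-odds link.
#'
#' @param n number of patients
#' @param hazard_ratio prior-vs-guided hazard ratio (>1 means longer guided
#'   PFS)
#' @param median_prior_weeks median PFS on the prior regimen
#' @param censor_weeks administrative censoring horizon for the guided arm
#' @param ipcy_sd spread of simulated i-PCY scores
#' @param ipcy_beta proportional-odds slope linking i-PCY to ordinal response
#' @param seed RNG seed
#' @return a [ClinicalCohort-class] with \code{prior_pfs_weeks},
#'   \code{prior_response}, \code{i_pcy}, \code{ordinal_response} columns
#' @export
simulateClinical <- function(n, hazard_ratio = 1, median_prior_weeks = 5.7,
                             censor_weeks = 60, ipcy_sd = 2, ipcy_beta = 1,
                             seed = 1L) {
  set.seed(seed)
  lamPrior <- log(2) / median_prior_weeks
  lamGuided <- lamPrior / hazard_ratio
  priorPfs <- stats::rexp(n, lamPrior)
  raw <- stats::rexp(n, lamGuided)
  ongoing <- raw > censor_weeks
  pfs <- pmin(raw, censor_weeks)
  ipcy <- stats::rnorm(n, 0, ipcy_sd)
  # proportional odds: cutpoints at -1, 0, 1 on the latent scale
  cuts <- c(-1, 0, 1)
  pGE <- vapply(cuts, function(ct) stats::plogis(ipcy_beta * ipcy - ct),
                numeric(n))  # P(ordinal >= 2), >= 3, >= 4
  u <- stats::runif(n)
  ordResp <- 1L + rowSums(u < pGE)
  records <- data.frame(
    patient_id = sprintf("PT%03d", seq_len(n)),
    diagnosis = "simulated",
    overall_response = CLINICAL_RESPONSES[ordResp],
    ordinal_response = ordResp,
    pfs_weeks = pfs, ongoing = ongoing,
    prior_response = ifelse(stats::runif(n) < 0.25, "responder",
                            "non-responder"),
    prior_pfs_weeks = priorPfs,
    i_pcy = ipcy, stringsAsFactors = FALSE)
  new("ClinicalCohort", records = records)
}
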