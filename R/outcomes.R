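#' Kaplan-Meier curve and median survival
#'
#' Product-limit estimator via \code{survival::survfit}. The median is the
#' smallest time at which the estimated survival drops to 0.5 or below; when
#' the curve never reaches 0.5 (e.g. heavy censoring) the median is the
#' \code{NA} sentinel. Ongoing responses are handled upstream by coding them
#' as censored (\code{events = FALSE}).
#'
#' @param times positive follow-up times
#' @param events logical; TRUE = progression/death observed, FALSE = censored
#' @return list with \code{time}, \code{surv} (step function values),
#'   \code{n_risk}, \code{n_event}, \code{median} (NA when undefined), and
#'   the underlying \code{survfit} object as \code{fit}
#' @export
kmCurve <- function(times, events) {
  if (!length(times)) stop("empty survival input")
  stopifnot(length(times) == length(events))
  fit <- survival::survfit(survival::Surv(times, as.integer(events)) ~ 1)
  # smallest time with S(t) <= 0.5 (survfit's own median averages across
  # exact-0.5 plateaus, a different convention)
  hit <- fit$surv <= 0.5 + 1e-9
  med <- if (any(hit)) fit$time[which(hit)[1]] else NA_real_
  list(time = fit$time, surv = fit$surv, n_risk = fit$n.risk,
       n_event = fit$n.event, median = med, fit = fit)
}

#' Log-rank test and O/E hazard ratio
#'
#' Mantel-Cox log-rank chi-square via \code{survival::survdiff}, with the
#' hazard ratio estimated as (O1/E1)/(O2/E2) from the observed and expected
#' event counts (Mantel-Haenszel variant optionally). The 95\% CI uses the
#' usual log-scale approximation with variance 1/E1 + 1/E2.
#'
#' @param times1,events1 first group's follow-up times and event indicators
#' @param times2,events2 second group's
#' @param method \code{"OE"} (default) or \code{"MH"} (Mantel-Haenszel,
#'   exp(U/V) with U, V from the log-rank statistic)
#' @return list with \code{chisq}, \code{p}, \code{hr} (hazard of group 1
#'   relative to group 2), \code{hr_ci}
#' @export
logrankHR <- function(times1, events1, times2, events2,
                      method = c("OE", "MH")) {
  method <- match.arg(method)
  time <- c(times1, times2)
  event <- as.integer(c(events1, events2))
  grp <- rep(1:2, c(length(times1), length(times2)))
  sd <- survival::survdiff(survival::Surv(time, event) ~ grp)
  chisq <- sd$chisq
  p <- stats::pchisq(chisq, df = 1, lower.tail = FALSE)
  O <- sd$obs; E <- sd$exp
  hr <- if (method == "OE") {
    (O[1] / E[1]) / (O[2] / E[2])
  } else {
    V <- if (is.matrix(sd$var)) sd$var[1, 1] else sd$var
    exp((O[1] - E[1]) / V)
  }
  seLog <- sqrt(1 / E[1] + 1 / E[2])
  ci <- exp(log(hr) + c(-1, 1) * stats::qnorm(0.975) * seLog)
  list(chisq = chisq, p = p, hr = unname(hr), hr_ci = unname(ci))
}

#' One-sided McNemar test with continuity correction
#'
#' For a paired 2x2 response table with discordant cells b (responded on the
#' prior regimen only) and c (responded on the new regimen only):
#' chi-square = (max(|b - c| - 1, 0))^2 / (b + c), and the one-sided p-value
#' for improvement under the new regimen (c > b) is half the upper chi-square
#' tail. When the discordance runs the other way the one-sided p is the
#' complementary half-tail; b + c = 0 gives p = 1.
#'
#' @param b,c discordant counts
#' @return list with \code{statistic} and \code{p}
#' @examples
#' mcnemarOneSided(b = 0, c = 11)  # statistic 100/11, p ~ 0.0013
#' @export
mcnemarOneSided <- function(b, c) {
  stopifnot(b >= 0, c >= 0)
  if (b + c == 0) return(list(statistic = 0, p = 1))
  stat <- max(abs(b - c) - 1, 0)^2 / (b + c)
  halfTail <- stats::pchisq(stat, df = 1, lower.tail = FALSE) / 2
  p <- if (c > b) halfTail else if (c < b) 1 - halfTail else 0.5
  list(statistic = stat, p = p)
}

#' Paired 2x2 cells from marginal responder counts
#'
#' Clinical reports often print only the margins of a paired response table
#' (responders on each regimen out of n) plus the discordant cell that is
#' zero. Given the margins and the prior-only discordant count b, the
#' remaining cells follow: a = respondersPrior - b, c = respondersNew - a,
#' d = n - a - b - c.
#'
#' @param respondersNew,respondersPrior responder counts on each regimen
#' @param n number of paired patients
#' @param discordantPriorOnly the b cell (default 0)
#' @return list with cells \code{a}, \code{b}, \code{c}, \code{d}
#' @export
pairedTableFromMargins <- function(respondersNew, respondersPrior, n,
                                   discordantPriorOnly = 0) {
  b <- discordantPriorOnly
  a <- respondersPrior - b
  cc <- respondersNew - a
  d <- n - a - b - cc
  if (min(a, b, cc, d) < 0) stop("inconsistent margins for a paired 2x2 table")
  list(a = a, b = b, c = cc, d = d)
}

#' Cross-product odds ratio for a 2x2 contingency table
#'
#' OR = (r1 (n2 - r2)) / ((n1 - r1) r2). A zero cell yields the infinity
#' sentinel unless the Haldane-Anscombe +0.5 correction is requested.
#'
#' @param responders1,n1 responders and total in group 1
#' @param responders2,n2 responders and total in group 2
#' @param haldane add 0.5 to every cell
#' @return odds ratio (possibly \code{Inf})
#' @examples
#' contingencyOddsRatio(15, 17, 4, 17)  # 24.375
#' @export
contingencyOddsRatio <- function(responders1, n1, responders2, n2,
                                 haldane = FALSE) {
  a <- responders1; b <- n1 - responders1
  c <- responders2; d <- n2 - responders2
  if (haldane) { a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5 }
  if (b * c == 0 && !haldane) return(Inf)
  (a * d) / (b * c)
}

#' PFS-ratio benefit analysis (patients as their own control)
#'
#' The PFS ratio is the progression-free survival on the new regimen divided
#' by the PFS on the patient's most recent prior regimen; a ratio of 1.3 or
#' higher (boundary inclusive) counts as clinical benefit. The null
#' hypothesis that 15\% or fewer patients attain such a ratio is tested with
#' an exact one-sided binomial test.
#'
#' @param pfs,priorPfs paired PFS values (weeks)
#' @param benefitThreshold ratio counting as benefit (default 1.3)
#' @param nullRate null benefit rate (default 0.15)
#' @return list with \code{ratios}, \code{n_benefit}, \code{fraction},
#'   \code{p} (exact binomial, one-sided), \code{reject_null} (at 0.05)
#' @export
pfsRatioAnalysis <- function(pfs, priorPfs, benefitThreshold = 1.3,
                             nullRate = 0.15) {
  ok <- is.finite(pfs) & is.finite(priorPfs) & priorPfs > 0
  ratios <- ifelse(ok, pfs / priorPfs, NA_real_)
  nb <- sum(ratios >= benefitThreshold, na.rm = TRUE)
  n <- sum(ok)
  if (!n) stop("no usable paired PFS values")
  p <- stats::binom.test(nb, n, p = nullRate, alternative = "greater")$p.value
  list(ratios = ratios, n_benefit = nb, fraction = nb / n, p = p,
       reject_null = p < 0.05)
}

#' Association between i-PCY scores and clinical outcome
#'
#' Pearson correlation between the integrated pharmacoscopy score and the
#' ordinal best response (1=PD, 2=SD, 3=PR, 4=CR), plus a binary separation
#' of progressive disease from responders (PR or CR) at the
#' accuracy-maximising i-PCY cut, with the ROC over all cuts.
#'
#' @param ipcy numeric i-PCY scores
#' @param ordinalResponse integer 1..4 coding PD < SD < PR < CR
#' @return list with \code{r}, \code{p} (correlation test),
#'   \code{accuracy} (best binary PD vs PR/CR separation; excludes SD as in
#'   neither class), \code{cut}, \code{auroc}, \code{roc}
#' @export
ipcyOutcomeAssociation <- function(ipcy, ordinalResponse) {
  stopifnot(length(ipcy) == length(ordinalResponse),
            all(ordinalResponse %in% 1:4))
  ct <- stats::cor.test(ipcy, ordinalResponse, method = "pearson")
  keep <- ordinalResponse != 2
  pos <- ordinalResponse[keep] >= 3   # PR or CR
  x <- ipcy[keep]
  if (!any(pos) || all(pos)) {
    return(list(r = unname(ct$estimate), p = ct$p.value, accuracy = NA_real_,
                cut = NA_real_, auroc = NA_real_, roc = NULL))
  }
  cand <- sort(unique(c(x - 1e-9, x + 1e-9)))
  accs <- vapply(cand, function(t) mean((x > t) == pos), numeric(1))
  best <- which.max(accs)
  a <- auroc(x[pos], x[!pos], positiveSide = "high")
  grid <- seq(0, 1, length.out = 101)
  list(r = unname(ct$estimate), p = ct$p.value, accuracy = accs[best],
       cut = cand[best], auroc = a,
       roc = data.frame(fpr = grid, tpr = rocStep(x, pos, grid)))
}

#' Read a clinical outcome table
#'
#' @param path CSV with at least \code{patient_id}, \code{overall_response},
#'   \code{pfs_weeks}, \code{ongoing} (logical or Yes/No)
#' @return a [ClinicalCohort-class]
#' @export
readClinicalTable <- function(path) {
  r <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (is.character(r$ongoing)) r$ongoing <- r$ongoing %in% c("Yes", "yes", "TRUE")
  if (!"ordinal_response" %in% names(r))
    r$ordinal_response <- match(r$overall_response, CLINICAL_RESPONSES)
  new("ClinicalCohort", records = r)
}

#' Clinical endpoint summary of a cohort
#'
#' Computes the standard endpoint set: responder count (CR or PR),
#' progressive-disease count, Kaplan-Meier median PFS with ongoing responses
#' censored, and (when prior-regimen margins are available) the cross-product
#' odds ratio and one-sided continuity-corrected McNemar test against the
#' prior regimen.
#'
#' @param cohort a [ClinicalCohort-class]
#' @param respondersPrior responders on the prior regimen (count); when NULL,
#'   taken from a \code{prior_response} column if present
#' @param discordantPriorOnly the prior-only discordant cell b (default 0)
#' @return list with \code{n}, \code{responders}, \code{pd_count},
#'   \code{ongoing}, \code{km_median}, and when margins are known
#'   \code{odds_ratio}, \code{mcnemar}
#' @export
outcomeSummary <- function(cohort, respondersPrior = NULL,
                           discordantPriorOnly = 0) {
  r <- clinicalRecords(cohort)
  n <- nrow(r)
  resp <- sum(r$overall_response %in% c("CR", "PR"))
  pd <- sum(r$overall_response == "PD")
  km <- kmCurve(r$pfs_weeks, !r$ongoing)
  out <- list(n = n, responders = resp, pd_count = pd,
              ongoing = sum(r$ongoing), km_median = km$median)
  if (is.null(respondersPrior) && "prior_response" %in% names(r))
    respondersPrior <- sum(r$prior_response == "responder")
  if (!is.null(respondersPrior)) {
    out$odds_ratio <- contingencyOddsRatio(resp, n, respondersPrior, n)
    cells <- pairedTableFromMargins(resp, respondersPrior, n,
                                    discordantPriorOnly)
    out$mcnemar <- mcnemarOneSided(cells$b, cells$c)
    out$paired_cells <- cells
  }
  out
}

#' The 17-patient guided-treatment clinical cohort
#'
#' The packaged clinical outcome table of the 17 patients who received
#' ex-vivo-screen-guided treatment: diagnosis, best overall response, PFS in
#' weeks, and whether the response was ongoing at the interim censoring date
#' (ongoing responses are right-censored in survival analyses).
#'
#' @return a [ClinicalCohort-class]
#' @export
guidedCohort <- function() {
  path <- system.file("extdata", "clinical_guided_17.csv",
                      package = "pharmacoscopy", mustWork = TRUE)
  readClinicalTable(path)
}
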