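# Independent textbook oracles, coded separately from the package internals.

# Product-limit estimator by direct recursion over distinct event times.
kmOracle <- function(times, events) {
  ord <- order(times)
  t <- times[ord]; e <- events[ord]
  ut <- sort(unique(t[e]))
  s <- 1
  surv <- numeric(length(ut))
  for (i in seq_along(ut)) {
    atRisk <- sum(t >= ut[i])
    d <- sum(t == ut[i] & e)
    s <- s * (1 - d / atRisk)
    surv[i] <- s
  }
  hit <- surv <= 0.5 + 1e-9
  med <- if (any(hit)) ut[which(hit)[1]] else NA_real_
  list(time = ut, surv = surv, median = med)
}

# Mantel-Cox log-rank chi-square by direct summation over risk sets.
logrankOracle <- function(t1, e1, t2, e2) {
  t <- c(t1, t2); e <- c(e1, e2)
  g <- rep(1:2, c(length(t1), length(t2)))
  ut <- sort(unique(t[e]))
  O1 <- E1 <- V <- 0
  for (tt in ut) {
    n <- sum(t >= tt); n1 <- sum(t >= tt & g == 1)
    d <- sum(t == tt & e); d1 <- sum(t == tt & e & g == 1)
    if (n < 2) next
    O1 <- O1 + d1
    E1 <- E1 + d * n1 / n
    V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  if (V <= 0) return(list(chisq = 0))
  list(chisq = (O1 - E1)^2 / V)
}

# AUROC by exhaustive pair enumeration (ties 0.5), positives at high values.
aurocOracle <- function(pos, neg) {
  s <- 0
  for (p in pos) for (q in neg)
    s <- s + if (p > q) 1 else if (p == q) 0.5 else 0
  s / (length(pos) * length(neg))
}

# One-sided continuity-corrected McNemar p via the normal tail
# (chi-square_1 upper tail = 2 * P(Z > sqrt(stat))).
mcnemarOracle <- function(b, c) {
  if (b + c == 0) return(1)
  stat <- max(abs(b - c) - 1, 0)^2 / (b + c)
  half <- stats::pnorm(sqrt(stat), lower.tail = FALSE)
  if (c > b) half else if (c < b) 1 - half else 0.5
}

# Exact binomial upper tail by direct summation of the pmf.
binomTailOracle <- function(k, n, p) sum(stats::dbinom(k:n, n, p))

# Brute-force per-well RBF recomputation from the raw counts of a well table.
rbfOracle <- function(wellsDf, patient, marker, drug) {
  sub <- wellsDf[wellsDf$patient_id == patient & wellsDf$marker == marker, ]
  ctl <- sub[sub$drug == "DMSO", ]
  cf <- numeric(0)
  for (i in seq_len(nrow(ctl))) {
    tot <- ctl$n_viable_marker_pos[i] + ctl$n_viable_marker_neg[i]
    if (tot > 0) cf <- c(cf, ctl$n_viable_marker_pos[i] / tot)
  }
  ctlMean <- mean(cf)
  trt <- sub[sub$drug == drug, ]
  out <- data.frame(conc = numeric(0), rbf = numeric(0))
  for (i in seq_len(nrow(trt))) {
    tot <- trt$n_viable_marker_pos[i] + trt$n_viable_marker_neg[i]
    if (tot > 0)
      out <- rbind(out, data.frame(conc = trt$concentration_um[i],
                                   rbf = (trt$n_viable_marker_pos[i] / tot) / ctlMean))
  }
  byConc <- tapply(out$rbf, out$conc, mean)
  mean(byConc)
}
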