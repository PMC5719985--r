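---
title: "Methods: models, noise assumptions and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, noise assumptions and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(pharmacoscopy)
```

# Scope

This vignette documents the scientific and numerical decisions behind the
package: the scoring model for image-based ex vivo drug screens, the
response classifier for the AML drug-matrix design, the clinical endpoint
statistics, the synthetic-data generator whose output all property tests run
on, and the simplified image-analysis stage. It states what each component
assumes, which parameters matter, and where a design was genuinely open and
a choice had to be made.

# The scoring model

## Relative blast fraction

A well's RBF divides its viable marker-positive fraction by the mean such
fraction over the patient's DMSO control wells. The model assumptions are:

- **Controls define the baseline.** The DMSO wells' mean fraction estimates
  the untreated blast fraction; per-well control RBFs have mean 1 by
  construction (asserted as an invariant).
- **Fractions, not counts.** Only the within-well composition enters, so any
  per-well multiplicative factor on counts — seeding density, imaging
  position, focus drift — cancels. RBF is exactly scale invariant (tested).
- **Averaging order.** Per drug, replicate wells are averaged within each
  concentration first, then concentrations are averaged unweighted. This
  keeps an unequal loss of replicates at one concentration from reweighting
  the dose response.
- **Degenerate wells.** A well whose viable total is zero has an undefined
  fraction; it is excluded with a warning, never imputed. If all of a drug's
  wells are excluded the result is missing.

Per-drug significance is a two-tailed Welch two-sample t-test of the drug
wells' RBFs against the per-well control RBFs. Welch rather than pooled
variance because drug wells (typically 5) and controls (typically 16 per
plate) differ in number and, after a cytotoxic treatment, in variance. Raw
p-values are reported by default (alpha 0.05); Benjamini–Hochberg adjustment
within a patient × marker is available behind `adjust = "BH"`.

## Pharmacoscopy scores and i-PCY

Scores normalise per-drug mean RBFs as (1 − RBF) / max(1 − RBF), the max
taken **over drugs after replicate/concentration averaging** within one
patient × marker. Whether that max could instead be taken over individual
drug–concentration pairs was an open question; taking it after averaging
matches the order in which the procedure is described and makes the score of
a drug independent of how many concentrations were tested for other drugs.
When no drug beats control (max(1 − RBF) ≤ 1e−9) the normaliser is
undefined; all scores are set to 0 — "no ex vivo effect" — with a warning,
rather than dividing by a vanishing or negative number.

The i-PCY score sums the scores of the administered drugs over all measured
markers. Only administered drugs enter (not same-class proxies — the second
open question); missing drug × marker combinations are a hard error listing
the gaps, because silently dropping them would bias the sum toward zero.
Per-marker rows are kept separate throughout; cross-marker averages are
derived views, since per-marker discordance is itself diagnostically
informative.

Drug ranking is by ascending mean RBF with lexicographic tie-breaks, so
reports are bit-reproducible. Display tables cap RBF at 1.2 in a separate
column; raw values are never capped.

Hierarchical clustering of score profiles uses average linkage on
1 − Pearson correlation with pairwise-complete masking of missing values.
Correlation distance groups drugs by the *shape* of their response profile
across patients (mode of action), not its magnitude; average linkage avoids
single-linkage chaining on dense drug panels. Neither metric nor linkage is
canonical; both are recorded here as the package's choice.

# The AML matrix classifier

The 20-patient retrospective design screens each sample through a 5×5×5
concentration grid of the three first-line drugs (125 unique combination
points, 4 technical replicates), with three DMSO-normalised readouts per
point: RBF, relative total cell count, and relative total blast count.

The decision surface is axis-aligned per matrix point: threshold t_j,
orientation σ_j (which side is responder-like) and weight w_j. This follows
the counting interpretation — datapoints *above or below* the surface score
±1 — rather than a general linear discriminant. Numerical rules:

- σ_j marks the lower side responder-like iff the responders' training mean
  is below the non-responders' (ties default to the lower side).
- t_j is the midpoint of the two adjacent training values that maximises
  training accuracy; among accuracy ties the candidate nearest the midpoint
  of the class means is taken, then the smaller value. A point where all
  training values coincide takes the class-mean midpoint.
- w_j is the point's AUROC (Mann–Whitney convention, ties 0.5) under σ_j;
  if it falls below 0.5 the orientation is flipped and the weight becomes
  1 − AUROC, so orientation and weight are always consistent and
  w_j ∈ [0.5, 1]. The exact fitting objective of an "ideal" separating
  surface was not specified; this threshold-scan rule is declared as ours.

The integrated response score is Σ w_j s_j / Σ w_j with s_j = ±1; it is
bounded in [−1, 1] and flips sign exactly under swapping the class labels
(tested). Adding a point changes a score by 0.5 (s_new − score)/(Σw + 0.5) —
the exact dilution identity the tests assert.

Cross-validation holds out k patients per class (all combinations;
k = 2 on the 10+10 design gives C(10,2)² = 2025 runs — the run count is
itself checked). Within each run the surface *and* the classification cut
are refit on the remaining patients only; the cut is the midpoint between
the training classes' mean integrated scores, falling back to 0 when the
training means do not separate (whether the original analysis used a fixed
zero cut or a training-derived cut is not stated; the fallback makes the two
coincide exactly when separation fails). Held-out ROC curves are averaged
vertically on a 101-point FPR grid.

# Clinical endpoint statistics

- **Kaplan–Meier.** `survival::survfit` provides the product-limit curve;
  the median is the smallest time with S(t) ≤ 0.5 (float tolerance 1e−9),
  computed directly from the curve because `survfit`'s summary median
  averages across exact-0.5 plateaus — a different convention. "Ongoing
  response = Yes" maps to right-censoring at the recorded PFS; with that
  mapping the packaged 17-patient cohort's median is 22.6 weeks (tested
  against a hand-rolled product-limit oracle).
- **Log-rank / hazard ratio.** Mantel–Cox chi-square via
  `survival::survdiff`; HR = (O1/E1)/(O2/E2) by default with the
  Mantel–Haenszel exp((O1−E1)/V) variant available. Both are score-based
  approximations: at a true HR of 3 the O/E form is biased toward the null
  (recovered means around 2.6 in the package's simulations) and the MH form
  away from it. Cox partial-likelihood estimation is deliberately out of
  scope; the recovery checks therefore average the O/E estimate over 50
  simulated trials and test it against a band that accommodates the bias.
- **McNemar.** One-sided, continuity corrected:
  χ² = (max(|b−c|−1, 0))²/(b+c), p = half the upper χ²₁ tail when the
  discordance favours the new regimen, the complementary half-tail when it
  does not, 0.5 at b = c, and 1 at b = c = 0. When only the margins of the
  paired table are printed, `pairedTableFromMargins()` reconstructs the
  cells from the responder counts and the known zero discordant cell.
- **Odds ratio.** Plain cross-product; zero cells yield the infinity
  sentinel unless Haldane–Anscombe correction (+0.5 per cell) is requested.
  The confidence interval printed in the original report does not match a
  standard Woolf interval and its method is unreported; the package outputs
  the point estimate and makes no attempt to reverse-engineer the interval.
- **PFS ratio.** Benefit is ratio ≥ 1.3, boundary inclusive; the null of a
  ≤15% benefit rate is tested by an exact one-sided binomial test. Because
  per-patient prior PFS values are not published, this endpoint is validated
  on synthetic cohorts only.

# The synthetic-data generator

The generator writes the same long-format tables the scoring engine reads
and stores closed-form expected RBFs as ground truth:
E[RBF] = (1−k_on) / ((1−k_on)·f + (1−k_off)(1−f)) for blast fraction f and
realised kill probabilities k_on, k_off — so proportional killing gives
exactly 1 at any dose, and the empirical RBF of a null screen is 1 within
Monte-Carlo error (both tested).

Noise model, chosen once to reflect a realistic 384-well imaging screen:

- Initial cells per well: lognormal around 2000 with CV 0.25–0.35
  (seeding-density variation).
- Blast count: beta-binomial around f with overdispersion 0.002 (slight
  extra-binomial variation in composition).
- Survival: binomial thinning with Hill-type dose scaling
  kill(c) = kill_max · c/(c + EC50), h = 1, EC50 at the geometric mid of the
  tested range (`ec50 = 0` disables scaling for closed-form checks).
- **Count drift and block offset** (cohort generator): a per-patient linear
  log-scale drift across the well sequence (sd 0.4) and a per-patient
  control-block vs drug-well offset (sd 0.35, i.e. tens of percent — within
  the plate-effect range reported for image-based screens). Both move every
  absolute DMSO-relative count coherently and cancel exactly in within-well
  fractions. These two terms are what make the three readouts differ: RBF
  is immune, relative total blasts inherits the full offset, and relative
  total cells additionally dilutes the on-target signal by the
  marker-negative fraction and confounds it with non-specific toxicity.
  Without them, integrating 125 matrix points averages away well-level noise
  and all three readouts classify equally well — which is not how absolute
  counts behave on real plates.
- Patient heterogeneity: per-drug lognormal variation of kill probabilities
  (sd 0.3) and a per-patient sample-quality factor on non-specific kill
  (sd 0.5); blast fractions uniform on [0.3, 0.95].

Screen geometry presets: 139 drugs × 2 concentrations with five replicate
wells per drug in total (split 3 + 2 — the published description counts
five technical replicates in total, which also fits the stated 768
conditions per sample), and the 125-point × 4-replicate AML matrix. Control
wells default to 16 DMSO wells per plate (the per-plate control count is not
published).

The clinical generator draws exponential PFS with a configurable hazard
ratio between paired arms, censors administratively (ongoing = TRUE at the
horizon, 60 weeks by default — about the real interim follow-up window),
and samples ordinal responses through a proportional-odds link on a
simulated i-PCY score.

What the generator does **not** emulate: spatial well-neighbour correlation,
drug-class covariance beyond shared effect vectors, pharmacokinetics,
non-exponential survival, informative censoring, or cell-line-specific
morphology. Passing tests therefore demonstrate correctness of the
pipeline's logic under a plausible noise model, not performance on real
screens.

# The image stage

A deliberately simple, fully specified stand-in for a production
segmentation pipeline, used to validate the counts → RBF path end to end.

Rendering: intact nuclei are single Gaussian blobs (σ 3 px); dead cells are
3–5 displaced fragments (σ 1.5 px, radius 5.5–7.5 px, near-even angles) of
equal total intensity; marker-positive cells get an elevated marker-channel
blob; Gaussian read noise is added. Cells sit on a jittered grid whose
spacing guarantees that fragments of one cell stay within the grouping
radius while never entering a neighbour's.

Segmentation: Gaussian smoothing (σ 2 px) of the max-normalised DNA channel,
global Otsu threshold, connected components, minimum area 30 px, and
single-linkage grouping of component centroids within 15 px into cells.
A scale-invariant blank guard rejects wells whose foreground/background
mean contrast after thresholding is below 4: normalising a signal-free noise
image would otherwise hallucinate objects. Viability requires a single
non-fragmented component with solidity ≥ 0.85 (pixel area over convex-hull
area, half-pixel rim corrected) and area within [30, 400] px. These
morphological defaults are declared, not inferred from any reference
pipeline.

Marker gating: one-dimensional Otsu over cell-mean marker intensities, with
the threshold placed at the middle of the between-class-variance plateau
(the first-bin convention puts it inside the negative mode on gapped data).
The split is only trusted when the high mode is ≥ 3× brighter than the low
mode; an earlier design gated on the normalised between-class variance, but
that statistic is ~0.6 even for unimodal Gaussian data and cannot detect
unimodality. Below the contrast gate the well is treated as unimodal and a
fallback applies: positive only above the 0.99 intensity quantile *and* 2×
the well median — so all-negative wells yield zero positives. All gates are
ratio-based, keeping every call invariant to a common intensity scaling
(tested, including through the TIFF round trip, which stores channels
jointly max-normalised).

# Problem sizes of the property checks

The acceptance checks run at the sizes the methods are designed for: the
full 2025-run leave-2-per-class cross-validation on 10+10 cohorts (three
seeds for the outlier-recovery band); 20 seeds at 100 runs
(leave-1-per-class) for the three-readout ordering and the label-permuted
null — the null band concerns a mean accuracy and does not depend on k,
while the outlier band does, so only the latter uses the full design;
20 rendered wells for the image-stage concordance; 50 simulated trials of
200 patients per arm for hazard-ratio recovery; and 1000 random
tables/datasets for the statistic-vs-oracle agreement.

# Known limitations

- The classifier assumes two classes and complete per-point patient means;
  missing matrix points are not masked in the fit.
- The O/E hazard ratio is a score-based approximation, biased away from
  extreme true ratios; interpret it near 1, or use the recovery analyses'
  averaging approach.
- The i-PCY cut for separating progressive disease maximises accuracy on
  the data it is computed from; it is descriptive, not a validated
  prospective threshold.
- The image stage's parameters are tuned to its own renderer; applying it to
  real micrographs would require re-deriving the morphological windows.
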