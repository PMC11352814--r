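---
title: "Proteomic mortality prognosis in stable COPD: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Proteomic mortality prognosis in stable COPD: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`protomort` implements a complete prognostic-screening pipeline for plasma
proteomics in stable chronic obstructive pulmonary disease (COPD): given a
patients-by-proteins abundance table from two complementary platforms
(label-free LC-MS quantification and bead-based multiplex immunoassay) and
four-year survival metadata, it screens proteins for differential abundance
between survivors and non-survivors, annotates the hits functionally, and
builds conformal random-forest models of both mortality (categorical) and
days of survival (continuous). This vignette documents the statistical
machinery, the choices behind it, and what the synthetic cohort generator
does and does not emulate.

## The data model

Plasma proteomic matrices of this kind are small (tens of patients), wide
(hundreds of proteins), and systematically incomplete. Missingness in
label-free LC-MS is largely left-censored — low-abundance proteins fall
below the detection limit — so a missing cell carries information: the
value was probably low. The pipeline therefore treats missingness in two
distinct ways:

* **Quantitative branch.** Proteins detected in at least 80% of the
  patients of *each* outcome group are compared quantitatively. Their
  missing cells are filled by *minimum imputation*: each missing value of a
  protein receives 95% of that protein's minimum observed linear-scale
  value, placing it just below the protein's apparent detection limit. The
  factor (0.95) and the coverage threshold (0.80) are config parameters
  (`impute_min95()`, `compute_coverage_and_route()`); the imputation is
  per-protein rather than global because detection limits are
  protein-specific in LC-MS. Alternative readings (global minimum, a low
  percentile) are one-line changes via the `factor` argument.
* **Qualitative branch.** Proteins below the coverage threshold may still be
  informative as presence/absence patterns: detected in at least 80% of one
  group and at most 20% of the other (both fractions configurable). These
  are tested on their 2x2 detection table. Proteins qualifying for neither
  branch are reported as excluded and not tested.

All abundances are log2-transformed before quantitative analysis, which
symmetrizes the typically right-skewed distributions.

## Differential-abundance screening

**Quantitative.** Each eligible protein is compared between groups with a
pooled-variance two-sample t-test when both groups pass a Shapiro–Wilk
normality check at alpha = 0.05, and a Mann–Whitney test otherwise. The
Shapiro–Wilk gate is a deliberate choice: it is the standard small-sample
normality test, and the gate level is a parameter. The effect size is the
log2 fold change (non-survivor mean minus survivor mean of log2 values) and
its equivalent percent change, %change = (2^log2FC − 1) x 100 — a bijection
the test suite verifies to 1e-6.

**Qualitative.** Presence/absence tables are tested with Barnard's
*unconditional* exact test, which is preferable to Fisher's exact test here
because the group sizes — not both margins — are fixed by design, and the
unconditional test is uniformly more powerful for such 2x2 designs at these
sample sizes. Tables are ordered by the pooled-variance Wald z statistic
(the common choice when no convexity trick is used) and the two-sided
p-value is the supremum of the tail probability over the unknown common
detection probability, evaluated on a grid of step 0.001 with the
boundaries excluded. The implementation is validated against a brute-force
enumeration oracle over all tables with the cohort margins and random
margins up to 25, to 1e-3. The effect size is the phi (Matthews)
coefficient of the detection table, signed so that positive means more
often detected in non-survivors; degenerate tables (no detections, or full
detection in both groups) return phi = 0, p = 1.

**Significance.** The differentially abundant protein (DAP) set is defined
by raw two-sided p < 0.05, without multiplicity correction — this pipeline
is a screening instrument for a pilot-sized cohort and several of the
interesting effects sit just under 0.05, which any correction would
erase. A Benjamini–Hochberg column is emitted alongside for reference but
does not drive the DAP set. Whether screening p-values should be one- or
two-sided is genuinely open at this cohort size; two-sided is the
conservative default used throughout.

## Functional annotation

DAPs are assigned to one of seven functional categories (lipid metabolism,
hemostasis, cytokines/inflammatory mediators, complement, adaptive
immunity, other immune-related, orphan) from a packaged lookup table
derived from Reactome/UniProt annotation of the plasma proteins recurrently
implicated in COPD mortality. Unknown proteins fall back to *orphan* with a
warning rather than failing, because annotation must never block the
statistics. A protein–protein edge list (with singleton rows for unlinked
proteins) can be exported for rendering in external network viewers; no
live database queries are performed, trading freshness for byte-level
reproducibility.

## Predictive modeling

The predictive core is an **aggregated conformal predictor (ACP)** wrapped
around random forests (200 trees, `mtry = floor(sqrt(k))`, minimum split
size 2, balanced class weights), with 10 sub-models whose calibration sets
are drawn by bootstrap: each sub-model trains on a bootstrap sample and
calibrates on the out-of-bootstrap rows. Per-class p-values are combined
across sub-models by the median, and the prediction set at confidence 0.8
contains every class with aggregated p > 0.2. A prediction is *conclusive*
when the set is a singleton; the fraction of conclusive predictions is the
*coverage* reported next to sensitivity and specificity.

Choices worth spelling out:

* **Nonconformity.** For classification, 1 − predicted probability of the
  true class; for regression, the absolute residual normalized by a local
  difficulty estimate: the mean absolute out-of-bag training residual among
  the 15 nearest training neighbors in standardized feature space, floored
  at 0.01 standard deviations of the outcome. Both are the standard
  textbook choices and are isolated behind the bundle objects so they can
  be swapped.
* **Pooled vs class-conditional calibration.** Class-conditional (Mondrian)
  calibration gives per-class validity, but with ~30 patients and a
  rebalanced minority of ~11, a sub-model's per-class calibration set holds
  only 3–5 scores, so the smallest attainable class p-value, 1/(n+1),
  already exceeds the 0.2 inclusion threshold: every prediction set keeps
  both classes and coverage is identically zero. The default is therefore
  pooled calibration, which preserves the marginal validity guarantee while
  producing conclusive predictions at realistic rates; `mondrian = TRUE` in
  `model_config()` restores class-conditional calibration for larger
  cohorts.
* **Calibration quantile.** The regression interval half-width uses the
  calibration score of rank `ceiling((n+1) * confidence)`, capped at the
  largest observed score (a finite cap keeps intervals informative at tiny
  calibration sizes; the validity test accounts for it empirically).
* **Rebalancing.** Class imbalance (23 survivors vs 11 non-survivors) is
  corrected by instance removal before fitting: *Instance Hardness
  Threshold* for the categorical outcome (drop the majority samples whose
  own-class cross-validated random-forest probability is lowest, until
  balance) and *All-KNN* for the continuous outcome (repeated
  edited-nearest-neighbour cleaning with k = 1, 2, 3, removing majority
  samples with any dissenting neighbor; the continuous path dichotomizes by
  event status for resampling only). The minority class is never reduced.
  This assignment of methods to outcomes is implemented exactly as stated
  in the protocol the pipeline follows, although the pairing is unusual;
  both methods are available to either path via `model_config()`.
* **Feature selection.** Univariate F scores (ANOVA F for classification,
  regression F otherwise), top-k with k = 10 by default — the "auto" width
  used by the reference protocol resolves to ten proteins. Constant
  features score zero; ties break by column order so selection is
  deterministic.
* **Determinism.** Every stochastic step (fold assignment, bootstrap
  draws, forest fitting, permutations) is seeded from the single
  `model_config()` seed (default 46) through a deterministic child-seed
  scheme; the full pipeline is bit-reproducible, which the acceptance
  suite asserts.

**Internal validation** is stratified 5-fold cross-validation with the
*entire* pipeline — rebalancing, feature selection, conformal fitting —
re-run inside each training fold, so no information from a held-out fold
can influence the model that predicts it (a planted leak-detector feature
in the test suite guards this). Out-of-fold prediction sets are pooled.
Permutation importance permutes one selected feature at a time in the
held-out fold (20 permutations) and records the mean degradation of fold
accuracy (classification) or Q² (regression).

## Evaluation

Sensitivity, specificity and MCC are computed **over conclusive predictions
only**, with the conclusive fraction reported separately as coverage. This
is the only reading under which a coverage below 1 can coexist with
perfect specificity in the same summary row, and it reflects conformal
practice: an inconclusive prediction is an abstention, not an error.
Predictive values and overall accuracy are then re-expressed at arbitrary
prevalence via the Bayes identities

$$PPV = \frac{Se\,\pi}{Se\,\pi + (1-Sp)(1-\pi)},\qquad
  NPV = \frac{Sp\,(1-\pi)}{Sp\,(1-\pi) + (1-Se)\,\pi},\qquad
  Acc = Se\,\pi + Sp\,(1-\pi),$$

evaluated by default at the cohort's own 4-year mortality (32%) and at the
literature rate from a large multicohort COPD collaboration (47%).
Re-adjustment at the empirical conclusive-set prevalence reproduces the
raw confusion-matrix values exactly, which the suite asserts as an
algebraic identity. Metrics are rounded to two decimals and rates to
integer percent in report output.

Continuous models report R² (resubstitution), Q² (1 − PRESS/TSS from
out-of-fold predictions) and conformal accuracy (fraction of prediction
intervals containing the true days of survival).

## The synthetic cohort generator

No raw proteomic matrix of this design is publicly deposited, so the
package ships a generator (`generate_cohort()`) that emulates the study
conditions and makes every stage testable end to end. Its defaults *are*
the study geometry: 23 survivors and 11 non-survivors, 300 LC-MS proteins
plus 63 multiplex analytes (363 features), left-censored missingness at the
per-protein 12% quantile plus 3% uniform dropout — which routes roughly 210
of 363 proteins to the quantitative branch, close to the 208/363 geometry
of the emulated design — ten planted quantitative effects of 2 log2 units
(random sign), ten planted presence/absence effects (detection 0.9 vs 0.1),
and a 1460-day follow-up. Days of survival for non-survivors are drawn from
an exponential waiting time truncated at the horizon whose rate increases
log-linearly in a latent risk score built from the planted markers; the
generating protocol gives no survival model, and this is the simplest
mechanism that links both the categorical and the continuous outcome to the
planted signal. A frequent-exacerbator flag is drawn with outcome-dependent
probability (7/23 vs 7/11 in expectation) so stratified mortality summaries
are exercisable.

What the generator does *not* emulate: peptide-to-protein rollup, plate
and batch effects, inter-platform calibration differences, heavy-tailed or
correlated protein co-variation, and informative censoring of follow-up.
Passing tests on synthetic cohorts therefore demonstrate that the
machinery is correct and calibrated under its stated assumptions — not
that the biological effect sizes of any real cohort will reproduce.

## Problem sizes used in the test suite

The suite validates conformal coverage guarantees on cohorts of 700
patients (200 training, 500 test points), screening calibration over 100
replicate 34-patient cohorts, and the Barnard kernel exhaustively over all
288 tables with the cohort margins plus randomized larger margins. These
sizes give binomial standard errors small enough for three-sigma bounds
while keeping the default test run in the low tens of seconds.

## Known limitations

* The Barnard p-value maximizes over a fixed nuisance grid (step 0.001);
  pathological tables could in principle peak between grid points, though
  the enumeration oracle bounds the error below 1e-3 across all tested
  margins.
* With pooled calibration, per-class conformal validity is not guaranteed
  under extreme imbalance — only marginal validity is; the Mondrian switch
  exists for cohorts large enough to afford it.
* Permutation importance on 7-patient held-out folds is coarse (accuracy
  moves in steps of 1/7); importances should be read as rankings, not
  effect sizes.
* The regression interval cap at the maximum calibration score slightly
  deflates nominal coverage when calibration sets are very small; the
  empirical validity tests include this effect.
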