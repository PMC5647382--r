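---
title: "Designing and applying minimal DNA methylation signatures"
author: "minsig package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing and applying minimal DNA methylation signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(minsig)
```

## The problem

Genome-scale DNA methylation arrays resolve the molecular subgroups of
tumours such as medulloblastoma (WNT, SHH, Grp3, Grp4) with high
confidence, but they need hundreds of nanograms of good-quality DNA.
Archival clinical material — FFPE sections, cytospin nuclear preparations,
decade-old trial biopsies — rarely meets that bar. `minsig` implements the
alternative: distil the genome-scale signal into a minimal panel of CpG
loci (17 by default) that can be measured by multiplexed bisulfite PCR and
single-base primer extension on degraded, low-input DNA, and make the
resulting classifier *multiply redundant*, so that losing several loci in
a poor sample does not change the subgroup call.

The package covers the whole arc: subgroup discovery on a training
beta-value matrix, candidate triage, fusion-ranked panel selection,
redundancy optimisation, confidence-thresholded classification with
imputation of missing loci, the assay-side QC cascade, and survival
comparison of the called subgroups. Because real patient matrices cannot
ship with the package, a synthetic-cohort generator reproduces the
statistical structure the pipeline assumes; every claim the test suite
makes is a claim about those synthetic cohorts.

## The synthetic cohorts

`simulate_cohort()` plants `n_subgroups` (default 4) disjoint sets of
`informative_per_subgroup` (default 150) loci in a universe of `n_loci`
(default 5000). Within a subgroup's informative set, half the loci are
hypermethylated in that subgroup and hypomethylated elsewhere and half the
reverse. Beta values are drawn from Beta distributions — `Beta(8, 2)`
(mean 0.8) for the methylated state, `Beta(2, 8)` for the unmethylated
state, `Beta(2, 2)` for uninformative background — because array beta
values live on [0, 1] with exactly this bimodal character. The planted
one-vs-rest mean shift is therefore about 0.6, comfortably above the 0.3
effect floor the recovery tests assert.

Source material drives degradation: each material tag carries an additive
truncated-Gaussian noise SD and a per-locus dropout probability (defaults:
frozen 0.01 / 0.005, FFPE 0.05 / 0.10, cytospin 0.07 / 0.15). These were
chosen as what is typically seen when moving from fresh-frozen array data
to archival material; the generator deliberately has no fragment-length or
PCR-chemistry model — degradation is represented purely as noise plus
missingness, which is the part the statistics downstream can see.
Survival is exponential per subgroup with administrative censoring at 60
months; default hazards give roughly 95% 5-year progression-free survival
in three subgroups and 82% in the Grp4-like one, the contrast the
log-rank machinery is meant to detect. Default cohort size is 50 samples
per subgroup (200 total), in line with a realistic training series.

What passing tests on these cohorts do **not** show: robustness to batch
effects, probe cross-reactivity, copy-number contamination of beta values,
or subgroups with unequal prevalence and overlapping signatures. The
generator can produce imbalanced or overlapping designs
(`samples_per_subgroup`, `overlap_informative`) for exploration, but the
defaults are the tested conditions.

## Subgroup discovery

`consensus_cluster()` runs non-negative matrix factorisation (Frobenius
objective, Lee–Seung multiplicative updates, 200 iterations maximum,
relative tolerance 1e-4) on the loci × samples matrix, over random
restarts (default 50) with 80% sample subsampling, for each candidate rank
k (default 2–8). Co-assignment frequencies form the consensus matrix;
average-linkage hierarchical clustering of `1 - C` yields assignments and
the cophenetic correlation per rank. Missing values are filled with locus
medians beforehand (training matrices are array-grade, nearly complete)
and clustering runs on the most variably methylated loci (default cap
10,000).

Rank selection needed one refinement. On cohorts with well-separated
subgroups the cophenetic coefficient saturates: every rank ≥ the true one
scores within a few thousandths of 1, and an overfactorised rank can edge
out the true one by a sliver while its silhouette collapses. A literal
"highest cophenetic" rule would then never consult the silhouette
tie-breaker, because exact floating-point ties do not occur. We therefore
treat all ranks whose cophenetic coefficient lies within `cophenetic_tol`
(default 0.01) of the maximum as tied, and resolve the tie by mean
silhouette width, then by the smaller rank. On the default synthetic
cohort this selects k = 4 in 10/10 seeds; without the tolerance band the
selection drifts to k = 5 while the silhouette at k = 4 is ~0.97 versus
~0.80 at k = 5.

Samples are internally reordered by identifier before any random draw, so
the partition is invariant to input order.

## Candidate selection: the moderated t

For each subgroup, loci are scored by a one-vs-rest moderated
t-statistic. Per-locus pooled variances $s_g^2$ on $d$ degrees of freedom
are shrunk towards a prior $s_0^2$ with weight $d_0$:

$$\tilde s_g^2 = \frac{d_0 s_0^2 + d\, s_g^2}{d_0 + d},\qquad
\tilde t_g = \frac{\Delta\beta_g}{\tilde s_g\sqrt{1/n_1 + 1/n_2}},$$

with $\tilde t_g$ referred to $t_{d+d_0}$ and Benjamini–Hochberg
adjustment across loci. The hyperparameters are fitted by moment-matching
the marginal distribution of $\log s_g^2$ under the scaled-inverse-χ²
model (mean and variance of $\log s_g^2 - \psi(d/2) + \log(d/2)$ identify
$s_0^2$ and $d_0$ through the digamma/trigamma functions; the trigamma is
inverted by Newton iteration). Setting `prior_df = 0` recovers the
ordinary two-sample t exactly; `prior_df = Inf` pins every variance to
$s_0^2$ — both limits are tested, and the fit is cross-checked against an
independent empirical-Bayes implementation. When the observed
log-variance dispersion does not exceed its sampling noise the fit
degenerates gracefully to $d_0 = \infty$.

`select_candidates()` keeps the top 50 loci per subgroup by $|\tilde t|$
(ties broken by locus id so runs are reproducible), after applying a
pluggable `design_filter` that stands in for primer-design triage; with
disjoint planted signals the pooled set is exactly 200 loci.

## Fusion ranking and redundancy optimisation

Candidates are ranked by fusing four learner families under stratified
10-fold cross-validation, in a two-stage hierarchy: WNT vs SHH vs merged
Grp3/Grp4, then Grp3 vs Grp4. The stage composition reflects the biology
— Grp3 and Grp4 are methylome neighbours and their separation deserves a
dedicated contrast — and each locus's overall rank is its best stage
rank. Per learner, per fold:

* **SVM** — linear kernel; importance is the mean absolute discriminant
  weight over one-vs-one class pairs.
* **ANN** — single-hidden-layer network (3 units, weight decay 0.01);
  importance is the held-out accuracy drop when the locus column is
  permuted.
* **DT** — CART with Gini impurity; `rpart` variable importance, zero for
  unused loci.
* **BN** — naive Bayes over beta discretised into three methylation
  states (unmethylated < 0.25, hemimethylated, methylated > 0.75);
  importance is the class–locus mutual information, which is exactly the
  quantity a naive Bayes model gains from the locus.

Importances are averaged over folds, converted to ranks per learner, and
fused as the arithmetic mean of ranks — the simplest order-statistic
aggregation; nothing suggested weighting the learners. Loci are processed
in identifier order, making the ranking invariant to column order.

`redundancy_optimize()` turns the top-ranked panel into a *multiply
redundant* one. A panel is scored by its mean cross-validated accuracy
when each evaluation masks a uniform 0–6 random subset of panel loci
(masked values replaced by training-fold means). Mask draws come from a
dedicated deterministic generator so competing panels are scored on
identical masks (common random numbers — otherwise Monte Carlo noise
dominates swap decisions). Each greedy round tries swapping every panel
locus for the next-ranked alternative and keeps the best improving swap;
the search stops when no swap helps (at most 5 rounds). `n_iter = 0`
disables the optimisation and returns the top 17 by fused rank. The panel
size (17) and mask depth (6) are configuration defaults, not constants.

## Classification, imputation, thresholds

`train_models()` fits two linear SVMs with pairwise-coupled probability
calibration: a genome-scale model on the 10,000 most variable loci and
the signature model on the panel. The signature model stores the training
mean and ridge-regularised covariance (ridge 1e-3) of the panel betas on
the logit₂ scale with beta clipped to [0.01, 0.99] — a Gaussian model
fits transformed values far better than bounded fractions. The
genome-scale model imputes missing features by training medians instead;
a 10,000-dimensional Gaussian would be neither estimable nor needed
there.

`impute_missing_em()` replaces missing panel entries by iterated
conditional-expectation sweeps under that Gaussian (Gauss–Seidel over the
missing coordinates), whose fixed point is the joint conditional mean of
the missing block — verified against the Schur-complement closed form to
1e-6. Pooled rather than class-conditional statistics are used: at
classification time the class is unknown, and conditioning on a call
before imputing would circularly reinforce it.

`classify_sample()` applies the QC cascade in the fixed order: bisulfite
conversion control (failed or absent control → `FAIL/BISULFITE_FAIL`),
missing-loci rule (more than 6 of 17 → `FAIL/LOCUS_QC_FAIL`), then
imputation and prediction, with calls below the confidence threshold
(default 0.69) returned as `NC/BELOW_THRESHOLD`. Both thresholds ship as
defaults and can be re-derived: `calibrate_missing_threshold()` bootstraps
masked re-classification (the full procedure uses 10,000 draws) and takes
the largest mask size whose monotone-smoothed agreement with complete-data
calls stays ≥ 0.99; `calibrate_probability_threshold()` grid-searches (step
0.01) for the smallest threshold with zero misclassification above it.
The agreement tolerance (0.99) and error tolerance (0) are exposed because
nothing canonical fixes them.

## Assay records and QC

`beta_from_extension()` is the identity of the assay: the methylated
fraction is the methylated-allele share of extension signal,
β = m/(m+u), with a zero-signal locus yielding `NO_CALL`. The conversion
control targets an invariably unmethylated locus; apparent methylation
above 0.1 (configurable — no canonical cut-off exists) marks failed
conversion, and conversion failure dominates the QC taxonomy. Cohort
reports bin samples by input DNA (<2, 2–10, 10–50, 50–100, >100 ng).
Dispositions are mutually exclusive by construction, so they always
partition the cohort. `simulate_mixture_series()` reproduces the 0–100%
methylation control series used to accept amplicons by per-locus
linearity.

## Survival

`km_estimate()` and `logrank_test()` wrap the product-limit estimator and
k-group log-rank statistic (asymptotic χ² reference; the observed and
expected event counts are returned so small-sample users can judge).
Five-year PFS is read from the KM step function at 60 months,
right-continuous. Both the four-group comparison and a collapsed
Grp4-vs-rest contrast are supported, since the clinically interesting
question is whether the Grp4-like subgroup does worse.

## Numerical choices and degenerate inputs

* NMF updates add `.Machine$double.eps` to denominators; the objective is
  checked non-increasing in tests.
* Tie-breaks everywhere are `(statistic, locus_id)`, making every ranking
  deterministic under a fixed seed.
* A constant matrix (all per-locus variances zero) is a degenerate-fit
  error in `moderated_t_stats`; singular covariances are ridge-stabilised
  at training time.
* An assay record with both intensities zero at a locus is a `NO_CALL`,
  not a 0/0 beta.
* Hazard 0 is allowed in the survival generator (an all-censored group);
  negative hazards are errors.

## Problem sizes used by the checks

The test suite exercises the full default cohort (200 × 5000) where the
claim is about the default conditions — subgroup recovery over 10 seeds
(consensus run at ranks 2–6, 12 restarts, 60 NMF iterations, clustering
on the 2000 most variable loci), signature design over 10 seeds with the
shipped defaults, and 500-mask robustness of the trained classifier.
Module-level tests use smaller planted cohorts (typically 40–60 samples,
a few hundred loci) where the property under test does not depend on
scale. These sizes are the package's own choice of where each property is
informative.

## Known limitations

* The NMF consensus is sample-subsampled only; locus subsampling is not
  implemented.
* The "Bayesian network" learner is naive Bayes — richer network
  structure gave the fusion no purchase on a 200-locus candidate matrix
  and would bring a structure-learning dependency.
* EM imputation assumes the pooled Gaussian on the logit scale; a
  class-conditional variant is deliberately not the default (see above).
* The design filter is a stub interface: real primer design (multiplex
  compatibility, mass windows, amplicon chemistry) is outside the
  package's scope.
* Survival reporting is univariate KM/log-rank only — no Cox models, by
  design.
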