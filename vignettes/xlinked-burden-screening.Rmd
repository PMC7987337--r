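---
title: "Extreme-phenotype rare-variant screening on the X chromosome: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extreme-phenotype rare-variant screening on the X chromosome: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xburden)
```

## The design

`xburden` implements a discovery-and-validation pipeline for X-linked
susceptibility genes in a male extreme-phenotype case-control design. The
motivating setting is severe infectious disease in young men: cases are
hospitalised patients requiring mechanical or non-invasive ventilation
(clinical category 3--4), controls are infected but oligo-asymptomatic men
(category 0), and everyone in between is excluded so that the genetic
contrast is maximal. Because the cohort is male and the genes of interest are
X-linked, every subject is hemizygous: any non-reference call marks a
carrier, and no zygosity modelling is needed.

The pipeline has five analysis stages, each exposed as plain functions over
data frames and matrices:

1. **Boolean encoding** (`build_boolean_matrix`): a subjects x genes matrix
   where entry 1 means the subject carries at least one *qualifying* rare
   variant in that gene. A variant qualifies when its consequence is
   missense, splicing or loss-of-function and its reference-population
   allele frequency is at most 1% (a missing frequency counts as rare, since
   absence from a large exome aggregate is itself evidence of rarity). The
   collapse is deliberately boolean: with singleton-level rarity, counts
   beyond one carry little information and the 0/1 coding keeps every gene
   on the same scale.
2. **Cohort QC** (`pca_scores`, `flag_outliers`, `qc_cohort`): subjects
   deviating by more than five standard deviations from the mean on any of
   the first three principal components of the column-centered boolean
   matrix are removed before regression. Flagging is a single pass; the
   statistics are not recomputed after removal.
3. **Penalized screening** (`fit_weighted_lasso`, `cross_validate`,
   `rank_features`): class-weighted L1-penalized logistic regression over a
   penalty grid, with stratified 10-fold cross-validation, fold-aggregated
   confusion matrix and metrics, and a signed ranking of nonzero
   coefficients (positive = susceptibility, negative = protection).
4. **Exact-test validation** (`carrier_table`, `fisher_exact_two_sided`,
   `odds_ratio`, `summarize_carriers`): the selected gene's carrier-by-arm
   table is tested with a two-sided Fisher exact test, and carrier fractions
   are reported by age stratum and by functional class.
5. **Expression validation** (`fold_change_ddct`, `compare_groups_log_t`):
   agonist-induced expression is quantified by the Livak 2^-ddCt method
   against a housekeeping gene, and carrier groups are compared with an
   unpaired t-test on log-transformed fold changes.

## The model behind the screen

Let $x_i \in \{0,1\}^G$ be subject $i$'s gene-burden vector and
$y_i \in \{0,1\}$ the case indicator. The screen fits

$$\min_{\beta_0, \beta}\; -\frac{1}{n}\sum_{i=1}^n w_{y_i}\Big[y_i \log
\sigma(\eta_i) + (1-y_i)\log(1-\sigma(\eta_i))\Big] \;+\;
\lambda \lVert\beta\rVert_1, \qquad \eta_i = \beta_0 + x_i^\top \beta,$$

with the intercept unpenalized. Class weights follow the balanced convention
$w_c = n / (2 n_c)$: the minority class is up-weighted inversely to its
frequency while the effective sample size is preserved, so equal arms give
unit weights. Features are *not* standardized: boolean columns already share
a scale, and standardizing would up-weight near-constant genes.

### Solver

The optimizer is cyclic coordinate descent with soft-thresholding on a
quadratic majorization of the logistic loss (curvature bound $w_i/4$ per
observation, which dominates the true curvature everywhere, so every
coordinate step provably decreases the objective). Convergence is declared
when a full sweep changes the objective by less than `tol` (default 1e-7);
the solver errors rather than returning silently after `max_iter` (10,000)
sweeps. Penalty paths are solved warm-started from the previous penalty. At
$\beta = 0$ the optimal intercept is the weighted log-odds of the labels,
which is where the solver starts; consequently any
$\lambda \ge \lambda_{max} = \max_j |\tfrac1n \sum_i w_i x_{ij}(y_i - \bar
p)|$ returns the exactly-zero coefficient vector. The implementation is
cross-checked in the test suite against an independent proximal-gradient
(FISTA) solver, a brute-force grid minimizer, `glm` at $\lambda = 0$, and
glmnet. Between full sweeps the solver iterates the active (nonzero)
coordinate set to convergence — the standard acceleration for sparse
problems, and every step still decreases the objective.

### Penalty selection

The grid is log-spaced over $[\lambda_{max} \cdot r, \lambda_{max}]$, 50
points by default, with floor ratio $r = 10^{-4}$ when subjects outnumber
genes and $r = 0.01$ otherwise: with more genes than subjects the boolean
matrix is typically separable, and near-zero penalties yield degenerate,
slowly-converging, essentially unpenalized fits that carry no information
for gene ranking. The chosen penalty maximizes the mean fold accuracy,
with ties resolved to the larger (sparser) penalty — on boolean burden data
long stretches of the grid often produce identical predictions, and
preferring sparsity keeps the selected model interpretable. Folds are
stratified by class so that no training partition can lose an arm at these
sample sizes; the assignment is derived from the seed on subjects sorted by
identifier, making results invariant to row order. Hard labels use a 0.5
probability threshold. The fold-aggregated out-of-fold confusion matrix
yields accuracy, precision, sensitivity, specificity and ROC-AUC (the
Mann-Whitney statistic with midrank ties).

A caveat that matters for interpreting the cross-validated accuracy: the
accuracy *at the selected penalty* inherits the usual model-selection
optimism (the maximum of several noisy estimates). Under a label-permutation
null this shows up as a small upward bias (about 2--3 points at $n = 60$
over a 15-point grid). The CV estimator itself is calibrated: averaged over
the penalty grid, the mean fold accuracy is centered at the 0.5 null
baseline, which is what the package's calibration checks assert. Nested cross-validation
would remove the selection bias but is out of scope, as the screen's purpose
is gene ranking rather than honest effect-size reporting.

### Exact test

`fisher_exact_two_sided` conditions on both margins and evaluates the
hypergeometric point probabilities over the full support in log space; the
two-sided p-value is the sum of all point probabilities not exceeding the
observed one (relative slack 1 + 1e-7 against floating-point ties). On the
published young-male carrier table ([[129, 6], [104, 0]]) this gives
p = 0.0372, printed as 0.037; the one-sided value would be 0.031. The
companion odds ratio is oriented as carrier odds in the severe arm over the
asymptomatic arm and uses the Haldane-Anscombe 0.5 correction when a cell is
zero; a table whose carrier column is entirely empty has no defined odds
ratio and is flagged rather than corrected away.

### Carrier strata

`summarize_carriers` counts *distinct* patients (a patient with two
qualifying variants counts once) under two nested rules: the candidate rule
(rare or missing population frequency, qualifying consequence, CADD at or
above 12.28) and the functional rule (candidate variants whose
experimentally determined class is LOF or hypomorphic). The CADD threshold
is implemented as inclusive: the published roster counts a variant scored
exactly 12.28 among the candidate carriers, so a strict inequality would
contradict the published counts. Functional class is always an input
annotation — it encodes wet-lab results and is never computed. Percentages
are rounded to one decimal (round-half-even), matching the published
formatting (6.3%, 2.2%, 1.9%).

### Expression analysis

Technical replicates are averaged on the Ct scale before any differencing
(the standard Livak procedure), then
$\Delta Ct = Ct_{target} - Ct_{housekeeping}$ per condition,
$\Delta\Delta Ct = \Delta Ct_{stim} - \Delta Ct_{medium}$, and fold change
$= 2^{-\Delta\Delta Ct}$. Group comparison uses a pooled-variance Student t
on log2 fold changes (Welch via a flag); the t statistic and p-value are
invariant to the log base and to common positive scaling of both groups. No
replicate outlier rejection and no amplification-efficiency correction are
applied.

## The synthetic cohort generator

No individual-level sequencing data can ship with the package (the
motivating cohort sits behind a registration-gated national database), so
`generate_cohort` emulates the study conditions and is itself first-class,
tested code:

- 79 cases / 77 controls by default, all male, ages uniform on 20--59
  (an `n_older` option emits subjects aged 60+ to exercise the age filter);
  cases are assigned category 3 or 4, controls category 0.
- 300 X-chromosome genes with independent per-subject background burden at
  rate 0.02 per gene — the true background burden rate of the real cohort is
  not published; 0.02 gives roughly three carriers per gene at n = 156,
  typical of rare-variant collapsing matrices, and is exposed in the config.
- One planted susceptibility gene with carrier frequency 0.06 in cases and
  0 in controls, mirroring the observed roughly-6%-versus-none contrast.
- Qualifying records get log-uniform allele frequencies on [1e-6, 0.01]
  (about 10% emitted with a missing frequency, so the missing-AF pathway is
  exercised), CADD uniform on [12.28, 30], and consequences drawn from a
  missense-heavy mix. Distractor records (rare synonymous, common missense,
  CADD below 12.28) are sprinkled at rate 0.02 per subject-gene pair and
  must be ignored by a correct encoder.
- Genotypes are written as hemizygous single-allele calls (GT `1`) in a
  VCF 4.2 file; the reader also accepts diploid-coded calls, since male
  X-chromosome output is caller-dependent.
- Ct plates: housekeeping at 24 cycles in both conditions, targets at 28 in
  medium, dropping by 3 cycles (8-fold induction) on stimulation in
  non-carriers and by `3 - qpcr_effect_log2` in functional-variant carriers;
  Gaussian replicate noise of 0.2 cycles. Neutral-variant carriers behave
  like non-carriers, matching the wet-lab observation that not every rare
  missense variant is functional.

A fixed seed reproduces every output byte-for-byte. What the generator does
*not* emulate: population structure and relatedness (background burden is
i.i.d.), linkage between variants, genotyping error, batch effects between
recruitment waves, and covariate confounding. Passing tests on synthetic
cohorts therefore demonstrate correctness of the machinery and recoverability
of a planted signal under idealised sparsity — not robustness to the
ancestry and calling artifacts of real exome data, which is precisely why
the PCA outlier step and the exact-test validation stage exist.

## Numerical and degenerate-input choices

- PCA runs on the centered, unscaled matrix (shared 0/1 scale); component
  signs are fixed by making the largest-magnitude loading positive. An
  all-constant matrix is an error in `pca_scores` (there is nothing to
  project), while the `qc_cohort` wrapper treats it as "no outliers", since
  nothing can deviate.
- The outlier SD is the population SD of the scores; ties at exactly
  `k_sd` SDs are not flagged (strictly "more than").
- Exact-test evaluation never uses a normal approximation; tables up to the
  published cohort sizes enumerate in microseconds.
- Undefined metric ratios (zero denominators) are reported as `NA`, never 0.
- Multi-allelic VCF records are decomposed into one record per alternate
  allele before filtering.

## Problem sizes used by the packaged checks

The test suite and the acceptance script run entirely on synthetic data and
the packaged nine-row variant roster. Monte-Carlo checks use 100 replicate
cohorts at the full 156-subject, 300-gene design for planted-gene recovery,
200 label-permutation cohorts at n = 60, G = 30 for cross-validation
calibration, 2,000 null tables for exact-test level, and 2,000 null plates
for the expression t-test level; solver-versus-oracle comparisons use 20
random instances with n ≤ 30 and up to 5 genes. These sizes give Monte-Carlo
standard errors comfortably below the margins asserted.

## Known limitations

- The penalty parameterization is the per-sample-averaged objective above;
  published penalty values from other software parameterizations are not
  comparable and are not treated as reproducible targets.
- Single-gene validation only: no genome-wide multiple-testing correction is
  provided, because the design tests one pre-selected gene.
- The screen's cross-validated metrics on any *real* cohort depend on that
  cohort's LD, coverage and ancestry structure; the package makes no claim
  that synthetic-cohort performance transfers.
- No covariate adjustment (age, comorbidities) in the regression: the
  extreme-phenotype design handles age by restriction, not modelling.
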