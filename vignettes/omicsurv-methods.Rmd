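---
title: "Screening multi-omics survival markers with split-half resampling"
author: "omicsurv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening multi-omics survival markers with split-half resampling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(omicsurv)
```

## The problem

Given a cohort of cancer patients with right-censored overall survival and
several molecular platforms measured on (overlapping subsets of) the same
patients — miRNA/mRNA/protein expression, DNA-methylation beta values,
copy-number segment means, somatic mutation calls — which molecular features
carry prognostic information, which platform predicts survival best, and does
any of it add to what routine clinical covariates (gender, age, tumor grade,
tumor stage) already provide?

omicsurv answers this with a fully resampling-based screening pipeline:

1. **Ordered 3-fold cross-validation.** Patients are sorted by
   survival/follow-up time and dealt round-robin into three sets (178/178/177
   at a cohort size of 533), so each set has near-identical survival-time and
   vital-status composition. Each round trains on two sets and tests on the
   third; every patient is a test patient exactly once.
2. **Split-half marker selection.** On each training cohort, each feature is
   screened 100 times: the training patients are split in half at random, a
   survival association must be significant (p < 0.05) in the first half
   *and* reproduce in the second half to count. The number of passing
   iterations out of 100 is the feature's *selection frequency*; the top 10
   per approach are the platform's candidate markers.
3. **Exhaustive rank search.** For each rank r (number of marker covariates),
   every size-r subset of the candidates is fitted as a Cox
   proportional-hazards model on the training cohort and the subset with the
   highest training concordance index wins; the winner is then evaluated
   once on the held-out test set.
4. **Clinical integration.** A clinical-covariate-only Cox model is the
   reference; integrated models start from markers + clinical covariates and
   are pruned by backward AIC elimination; a multi-omics model pools the
   marker unions of all platforms.

## The three stratification approaches

All molecular values are first standardized to Z-scores,
$Z = (x - \bar{x}) / s$, with the per-feature mean and sample standard
deviation (n−1 denominator) estimated **on the training cohort's tumor
samples only** and applied unchanged to the test cohort. Fitting the
transform on the pooled cohort would leak test-set location/scale into
training; the training-only choice is the conservative reading of a
standardization rule stated only as "in the tumor samples", and it may shift
results slightly relative to pooled standardization.

- **Extreme score** (`extreme_score_selection()`): patients with Z > 1
  ("extremely high") versus Z < −1 ("extremely low"), compared by a
  two-group log-rank test. Both groups must contain at least 10 patients.
- **Mean score** (`mean_score_selection()`): the same contract with the
  threshold at the mean, Z > 0 versus Z ≤ 0. An exact zero is assigned to
  the low group — a measure-zero event for continuous data, but a
  deterministic rule is needed for reproducibility.
- **Extreme survival** (`extreme_survival_selection()`): patients who died
  within the first year (observed event, time ≤ 365 d) versus patients who
  lived beyond five years (time > 1825 d), compared feature-wise by a Welch
  t-test on the molecular values. A patient censored before day 365 is
  uninformative for "died within the first year" and belongs to neither
  group; a patient who *died* after day 1825 did live more than five years
  and is included in the long-surviving group. If either half of a split
  lacks 10 short or 10 long survivors the whole iteration is skipped and
  removed from the frequency denominator (reported as
  `n_iterations_effective`).
- **Combined** (`combined_selection()`): the union of the three top-10
  lists, hence up to 30 candidates.

One random half-split is drawn per iteration and shared by all features of a
platform — the natural reading of "the training cohort was randomly divided"
and two orders of magnitude cheaper than per-feature splits. Somatic
mutations are screened differently (`mutation_gene_selection()`): a single
log-rank test of carriers versus non-carriers of each gene (or each
individual variant) on the full training cohort, with the same p < 0.05 and
minimum-group-of-10 rules and no resampling.

No multiple-testing correction is applied across features: the split-half
replication itself is the error control (a null feature passes one iteration
with probability ≈ α² = 0.0025), and the frequency ranking orders features
by the stability of their association, not by a single p-value.

### Deterministic reporting rules

- Top-k ties are broken by frequency (descending), then the mean across
  passing iterations of the binding (larger) per-half p-value (ascending),
  then feature id — fully reproducible.
- A marker's direction of association (`high_better` / `high_worse`) is the
  majority survival ordering across its passing iterations (sign of the
  summed observed-minus-expected deaths for the log-rank approaches, sign of
  the t statistic for extreme survival); split majorities yield
  `undetermined`.
- All selection operations order patients by sorted id internally, so
  results are invariant to the column order of the input matrices, and a
  fixed `rng_seed` makes every run bit-reproducible.

## Survival machinery

- **Cox fits** go through `survival::coxph()` with the Efron approximation
  for tied event times — better than Breslow at the tie rates day-resolution
  data produces. Fits that fail to converge or hit a monotone likelihood
  (perfect separation) are returned flagged and skipped by the searches with
  a logged reason, never silently kept.
- **Concordance** (`concordance_index()`) uses Harrell's rule: pairs (i, j)
  are comparable when i has an observed event and $t_i < t_j$; a comparable
  pair is concordant when the earlier-failing patient has the higher risk
  score; tied risks count 1/2; pairs censored at equal times are not
  comparable. The implementation is a vectorized O(n²) pair count and is
  tested for exact agreement with an explicit pair-loop enumerator.
- **AIC** is −2·loglik + 2·k on the partial likelihood.
- The in-package log-rank and Welch statistics exist because the selection
  loops evaluate them ~10⁵ times per platform; both are tested for exact
  agreement with `survival::survdiff()` and `stats::t.test()`.

## Model search and integration

`best_model_per_rank()` enumerates size-r candidate subsets lexicographically
without materializing them. "Best on the training cohort" means the highest
training C-index — the pipeline's sole stated selection metric; AIC only
breaks exact C ties, then the lexicographically smallest covariate set. Each
subset is fitted on its own complete cases (patients missing any covariate of
that subset drop out of that fit and of its C evaluations); missing values
are never imputed anywhere in the package. The combined approach's pool of up
to 30 candidates makes full enumeration at rank 10 infeasible
(C(30,10) ≈ 3·10⁷), so its rank is capped at 6 (C(30,6) = 593 775, the worst
case the design accepts); an additional configurable `max_subsets` cap trims
the candidate pool (lowest-frequency candidates first) with a logged
downgrade when a search would exceed it.

`backward_aic_integration()` starts from all markers plus the clinical
covariates, fixes the complete-case rows of that initial set so AIC values
stay comparable across steps, and repeatedly removes the single covariate
whose removal minimizes AIC while that improves on the current model. The
AIC trace is strictly decreasing by construction and is returned for
inspection; tests verify agreement with `MASS::stepAIC()` and against the
exhaustive all-subsets minimum on small pools. Ordinal clinical covariates
enter as integer codes 1–4 (the smallest model consistent with treating
grade and stage as single features), gender as a 0/1 indicator, age in
years, all unscaled. The multi-omics model pools the platform marker unions
with platform-prefixed names (`mirna__x` and `mrna__x` stay distinct) and by
default contains markers only; clinical covariates can be included with a
switch.

## Copy-number and file handling

Gene-level copy number is derived from SEG segment tables by
overlap-length-weighted means: a gene's value for a patient is
$\sum_k w_k m_k / \sum_k w_k$ over all overlapping segments, with $w_k$ the
overlap length. This rule is deterministic, order-independent, and invariant
to splitting a segment into pieces of equal mean; overlapping segments
within one patient and chromosome are treated as an input error. Coordinates
are 0-based half-open throughout, strand is carried but ignored (copy number
is strand-agnostic), and overlap finding uses GenomicRanges. Features
quantified in half the patients or fewer are removed before analysis
(strictly more than `cohort_size/2` non-missing values are required).
Writers emit numerics with 17 significant digits so a write-then-read round
trip is bit-identical.

## The synthetic cohort generator

`simulate_cohort()` is the package's ground-truth factory, and its defaults
describe the cohort the pipeline targets: 533 patients, a censoring fraction
of 1 − 176/533 ≈ 0.67 (matching 357 alive / 176 deceased), stage frequencies
267/57/126/86, and whole-patient platform missingness matching the
availability profile (miRNA 493, mRNA 518, protein 454, CNV 511, methylation
477 of 533 tumors assayed, with 71/72/0/510/358 normal-tissue companions, of
which the generator produces the methylation and miRNA ones that the
methylation–expression report needs).

Mechanics: continuous platforms are i.i.d. standard normal per feature;
methylation is a logistic transform of a latent normal (optionally shifted
with tumor stage and anti-correlated with a paired expression feature —
the mir-21-like motif of tumor hypomethylation with elevated expression);
copy number is drawn per gene and also emitted as a SEG segment table plus
BED annotation whose mapping reproduces the gene values exactly; mutations
are Bernoulli per gene. Survival times follow a Weibull
proportional-hazards mechanism (shape 1 = exponential by default — the
simplest mechanism consistent with the Cox assumption), with log hazard
equal to the clinical terms plus every planted molecular term
(coefficients are per SD of the feature). Censoring is an independent
uniform horizon whose upper bound is solved numerically on the realized
event times to hit the target censoring fraction. Clinical effects default
to modest grade/stage/age hazards so the clinical-only reference model is
informative.

What the generator does **not** emulate: correlation structure between
features (no co-expression modules or LD), realistic copy-number breakpoint
geometry (segments coincide with gene intervals), batch effects, or
informative censoring. Passing tests therefore demonstrate that the
pipeline's machinery is correct and calibrated — planted effects are
recovered, null data stays at chance — not that any particular real cohort
will yield particular markers or C-index values.

## Numerical choices and degenerate inputs

- Sample standard deviation uses the n−1 denominator; zero-variance features
  are flagged and excluded from standardization and selection (logged, not
  fatal).
- A log-rank comparison with no events at all returns statistic 0, p = 1
  with a warning; features whose groups cannot reach the minimum size are
  simply never eligible.
- `fit_cox()` requires at least covariates + 2 complete cases and one event.
- Concordance with zero comparable pairs is an error (not NaN).
- The per-round selection seed is derived from the master seed as
  `master * 1000 + round`, kept below 2³¹, so any single round can be
  reproduced in isolation.

## Problem sizes used in the checks

The packaged test-suite exercises the pipeline at sizes chosen to make the
statistical properties sharp while keeping a full run in minutes: null
calibration runs the complete 3-round cross-validation on 533 patients with
500 features on each of two platforms and 100 selection iterations (ranks
capped at 3, combined at 2); planted-marker recovery uses 10 cohorts of 533
patients with 100 features and two planted markers at a hazard ratio of 3
per SD; search-versus-enumeration checks use pools up to 12 candidates and
ranks up to 4; backward-AIC floors are verified exhaustively on 8
covariates; concordance is checked against the pair enumerator on 100
random cohorts up to n = 200.

## Known limitations

- A single-split analysis (no cross-validation averaging) depends strongly
  on the particular random split; only cross-round averages are stable.
- At k = 3 the cross-round standard deviation is itself very noisy; it is
  reported because the report format calls for it, not because it is a good
  uncertainty estimate.
- Raw p < 0.05 with split-half replication controls per-feature error but
  the top-10 rule still selects *something* even under the null (with
  frequencies of 1–2); downstream ranks 1–2 models on null data sit at
  C ≈ 0.5, which is the designed behavior.
- The exhaustive search optimizes training C, so training C is biased
  upward; only test C is an honest performance estimate.
- Tie handling (Efron, Harrell 1/2-credit) is one of several defensible
  conventions; alternatives may differ in the third decimal.
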