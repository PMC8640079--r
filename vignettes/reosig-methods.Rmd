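---
title: "Qualitative REO signatures: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Qualitative REO signatures: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reosig)
```

## The method

Quantitative expression signatures inherit every normalisation and batch
artefact of the platform they were trained on. A *qualitative* signature
sidesteps this by using only within-sample orderings: for a pair of
miRNAs $(i, j)$ with expression $E_i, E_j$ in one sample, the relative
expression ordering (REO) is

$$ r_{ij} = \operatorname{sign}(E_i - E_j) \in \{-1, 0, +1\}, $$

which is invariant under any strictly increasing transformation of that
sample's values. A classifier built on REO features therefore transfers
across batches and normalisation schemes, and can be applied to a single
sample in isolation.

The discovery cascade implemented here has three stages, followed by
model fitting and evaluation:

1. **Reversed-stable screening** (`screen_reversed_stable()`). A pair is
   *reversed stable* at threshold $\theta$ if its REO agrees with the
   control-majority direction in at least a fraction $\theta$ of control
   samples *and* shows the opposite direction in at least a fraction
   $\theta$ of case samples. The default $\theta = 0.60$. All
   $m(m-1)/2$ pairs are scanned in fixed-size blocks (default 50,000
   pairs), so the full pair-by-sample feature matrix is never held in
   memory even for panels with millions of pairs.
2. **Forest importance ranking** (`rank_by_forest_importance()`). A
   100-tree random forest on the ternary features ranks screened pairs
   by mean decrease in Gini impurity (normalised to sum to one); the top
   400 proceed. Only the forest seed is pinned (default 16); the tree
   count is exposed because it is an ecosystem default, not part of the
   method.
3. **SVM-RFE with stratified cross-validation** (`svm_rfe_cv()`). A
   linear soft-margin SVM (cost 1) is trained on the surviving
   features; the feature with the smallest squared weight is removed,
   one per iteration. Each stratified fold (3 by default) contributes a
   held-out accuracy at every retained-set size; the chosen size is the
   *smallest* size attaining the maximal mean accuracy, and the
   reported subset is the one surviving to that size when elimination
   is re-run on all training data.

The final signature combines the selected pairs with two encoded
clinical covariates: age mapped to $\{-1, 0, +1\}$ at thresholds 70 and
80 years, and the APOE $\varepsilon4$ allele count (0, 1, 2). Four
canonical model configurations (`dlb_model_config(1:4)`) cross the two
feature sets (pairs-only vs. full signature) with two families: an SVM
searched over cost and kernel-width grids
$\{2\cdot10^{-4}, 2\cdot10^{-3}, 0.2, 2, 20, 200\}$ with RBF and linear
kernels, and an L2-regularised logistic regression searched over
$C \in \{10^{-4}, 10^{-3}, 10^{-2}, 10^{-1}\}$. Grid points are scored
by mean stratified 3-fold CV accuracy; ties resolve to the earliest
point in enumeration order.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| screening threshold $\theta$ | 0.60 | fraction | minimum class consistency; inclusive comparison (`>=`) |
| REO tie tolerance `epsilon` | 0 | expression units | exact equality defines a tie; widen only for quantised data |
| shortlist size `top_k` | 400 | pairs | forest-ranked pairs passed to RFE |
| RFE folds / cost / step | 3 / 1 / 1 | — | stratified folds, linear-SVM penalty, features removed per round |
| age thresholds | 70, 80 | years | ordinal three-class encoding, left-closed ([70, 80) maps to 0) |
| grid-search folds | 3 | — | stratified; the backend's ambient default is overridden |
| seeds | 16 | — | fold shuffling, forest, holdout; every stage records its seed |

## The synthetic cohort generator

`simulate_cohort()` exists so the whole cascade can be validated against
a known truth. It emulates, on the log2 scale:

* per-miRNA background baselines drawn uniformly from `[4, 12]` log2
  units with Gaussian measurement noise (`noise_sd`, default 0.5),
  class-independent;
* planted reversed pairs: per sample, the two members sit at
  $\pm$`pair_separation`$/2$ (default 1.5, i.e. three noise standard
  deviations) around the pair's per-sample level, oriented one way in
  controls and the opposite way in cases; the class-specific orientation
  is applied with probability `fidelity` (default 0.85) and flipped
  otherwise, independently per sample;
* a per-sample *pair level*: the pair's baseline plus a shared Gaussian
  component (`pair_level_sd`, default 4 log2 units) common to both
  members. This models the large between-sample variability of
  co-regulated transcripts. It cancels exactly in the within-pair
  difference, so it changes nothing about the planted ordering signal —
  but it is essential for identifiability: without it, a planted
  member's class-dependent shift makes it cross every bystander miRNA
  whose baseline lies inside the oscillation window, creating secondary
  reversed-stable pairs that are genuine reversals yet absent from the
  recorded truth. With the shared level, the planted list *is* the
  reversal structure, and recovery is a meaningful score;
* clinical covariates correlated with the label: integer ages truncated
  to [40, 100], controls centred at 72 and cases shifted by
  `age_case_shift` (default 3 years, sd 8); APOE $\varepsilon4$ allele
  counts $\sim \text{Binomial}(2, p)$ with $p = 0.12$ in controls and
  $0.20$ in cases; sex balanced and label-independent;
* batch/normalisation effects: `apply_monotone_distortion()` passes
  each sample through an independently drawn strictly increasing map (a
  positive affine map composed with a cubic warp centred on the sample
  median), preserving within-sample order exactly.

The default cohort — 150 cases, 150 controls, 100 miRNAs, 10 planted
pairs — is the reference condition used throughout the package's
validation; tests on reduced instances use 15–60 samples per class and
8–40 miRNAs so the suite runs in seconds. One master seed drives a
dedicated RNG stream per component, so adding draws to one component
never perturbs another's, and identical specs give bit-identical
cohorts.

**What the generator does not emulate.** Real miRNA panels have heavy
inter-miRNA correlation beyond the planted pairs, non-Gaussian noise,
missingness patterns, and probe-level artefacts; ages arrive in coarse
bins on some platforms; case/control labels carry diagnostic
uncertainty. Passing the synthetic recovery suites therefore shows that
the cascade's logic is correct and batch-invariant, not that any
particular accuracy will be achieved on a real cohort.

## Numerical choices

* **REO ties.** A tie ($E_i = E_j$ exactly) counts toward neither
  class's consistency numerator but stays in the denominator: a tie is
  evidence for neither ordering. At threshold 1.0 a single tied sample
  therefore excludes a pair.
* **Control-direction ties.** If exactly half the non-tied controls go
  each way, the direction breaks toward $+1$.
* **Threshold comparison** is inclusive (`>= 0.60`), exposed as a
  parameter.
* **Canonical pair order.** Pairs enumerate lexicographically over
  sorted miRNA ids; every downstream tie-break (forest ranking, RFE
  elimination, reporting) inherits this order, which makes the whole
  cascade reproducible bit-for-bit.
* **RFE weight ties.** Squared linear-SVM weights are rounded to 8
  significant digits relative to the largest weight before comparison;
  duplicated or mirrored ternary columns produce mathematically tied
  weights, and without rounding the elimination order would depend on
  floating-point summation order. Among tied features the one latest in
  canonical order is removed.
* **Probability calibration.** The SVM family maps decision values to
  case probabilities through a sigmoid fitted on out-of-fold decision
  values from the same seeded stratified folds used for grid search, so
  scores are deterministic functions of the data and seed. Both
  families classify at 0.5 on the calibrated score.
* **Logistic penalty.** The L2 path is fitted at the single value
  $\lambda = 1/(nC)$ without standardisation, matching the
  inverse-regularisation convention of the grids above. Single-feature
  designs are padded with a zero column to satisfy the backend's
  two-column minimum; the pad carries no information.
* **Fold allocation.** Within each class, a seeded shuffle is chunked
  into $k$ contiguous blocks whose sizes differ by at most one, larger
  blocks first — 135 cases and 230 controls in 3 folds give case counts
  (45, 45, 45) and control counts (77, 77, 76). The hold-out split
  sizes the test set as $\lceil f n \rceil$ and allocates per-class
  counts by largest remainder (169 cases and 288 controls at 20% give a
  34 + 58 test set).
* **Aggregate conventions.** Weighted F1 is the class-size-weighted
  mean of per-class F1 — the unique convention consistent with
  reporting both a case-positive SE and a control-positive SP.
  Across-fold standard deviations are reported in both the population
  (divide-by-$k$) and sample conventions; the population convention is
  the primary one. The 2×2 homogeneity test uses the Yates-corrected
  chi-squared statistic, clamped at zero.
* **AUC** is computed as the Mann–Whitney probability from midranks,
  which equals the trapezoidal area under the empirical ROC curve; the
  test suite verifies the equality against an independent
  implementation.

## Design choices where the design was open

* **Age boundary convention.** The three-class encoder is left-closed:
  an age exactly at a threshold falls in the upper class (70 maps to 0,
  80 maps to $+1$). Only the thresholds themselves are inherent to the
  method; the boundary is configurable.
* **Probe collapsing** averages probe rows per miRNA and handles both
  one-probe and multi-probe annotations; unmapped probes are dropped
  (with a count) rather than kept under probe ids, because all
  downstream pairing is by miRNA identity. Missing values are a hard
  error, never imputed — silent imputation would corrupt REO counts.
* **Redundant features and subset size.** With several features
  carrying the same reversal signal, mean CV accuracy can peak at a
  subset smaller than the full informative set (two fully redundant
  ternary features never outperform the better one, since tied votes
  cannot be split). The smallest-maximiser rule then deliberately
  returns the compact optimum. Consequently the selected subset is an
  *optimal* subset, not an exhaustive list of informative pairs; the
  elimination order, which the `svm_rfe` object retains, is the right
  place to look for near-equivalent alternates.
* **Command-line access** is provided as a thin script
  (`inst/cli/reosig.R`) over the exported functions: `simulate`,
  `screen`, `select`, `split`, `train`, `evaluate`.

## Known limitations

* Screening is marginal per pair: a pair whose reversal is informative
  only jointly with another pair will not pass the screen.
* The forest stage ranks features marginally-with-interactions but its
  importances are impurity-based and can favour correlated clusters.
* Exact floating-point equality defines REO ties; platforms that
  quantise expression should set `epsilon` accordingly.
* The evaluation module assumes a binary case/control design; multi-way
  differentials (e.g. against other dementias) are out of scope.
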