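---
title: "Methods: two-stage hierarchical classification of NPX proteomic profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-stage hierarchical classification of NPX proteomic profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(npxhier)
```

## The classification model

`npxhier` classifies samples of a plasma-proteomic feature table —
NPX (Normalized Protein eXpression) values, a relative log2 abundance
scale — into one of M phenotypes using a two-stage hierarchy guided by a
clinical taxonomy. The taxonomy partitions the phenotype labels into K
disjoint categories (equivalence classes); labels listed as *terminal*
(typically the healthy controls) form their own first-stage class and
skip the second stage.

The first-stage classifier f is trained on `(x, category(y))` over all
training samples. For each non-terminal category j, a second-stage
classifier g_j is trained only on the samples belonging to j. At
prediction time the full posterior over phenotypes is the product
mixture

$$P(\ell \mid x) = P_f(j(\ell) \mid x)\, P_{g_{j(\ell)}}(\ell \mid x),$$

where j(ℓ) is the category of phenotype ℓ and terminal phenotypes take
their first-stage probability directly. Each row of the resulting matrix
sums to 1 by construction, and summing the entries of a category
reproduces the first-stage category probability exactly — both are
tested invariants.

Two readings of the second-stage conditional are possible. Because g_j
is fitted only on category-j samples, we evaluate g_j's posterior at x
regardless of the first stage's realized decision; this is the only
reading that makes the mixture computable for soft first-stage outputs.
With a one-hot (hard-routing) first stage, the mixture degenerates to
"classify the category, then classify within it", which the test suite
checks against an explicit two-step oracle.

A category with a single phenotype present in training is fitted as a
pass-through node: its phenotype inherits the first-stage category
probability unchanged.

**Where the healthy class lives.** The first stage could treat healthy
as a fifth disease category or handle it separately. We make healthy a
*terminal first-stage class* (K = 5 first-stage classes for the
blood/psychiatric/metabolic/tumor taxonomy): the model's output is a
full probability vector over all phenotypes including healthy, and no
second-stage "healthy" group exists that could host it.

## Node classifiers

Every node is described by a `node_spec()`: an algorithm, its
hyperparameters, and a score-to-probability rule. Defaults mirror the
final design this package implements: perceptron (first stage),
extremely randomized trees (blood), hinge-loss SGD linear classifier
(psychiatric), ridge classifier (metabolic), logistic regression
(tumor); `default_node_specs()` matches these to a taxonomy by category
name. Logistic regression is delegated to `nnet::multinom` and the tree
ensembles to `ranger`; the perceptron (averaged multiclass), ridge
classifier (one-vs-rest penalized least squares on ±1 indicators) and
hinge-SGD classifier are implemented in the package, as R's ecosystem
has no equivalents of these scikit-style decision-score classifiers.
Linear algorithms standardize features internally with training-set
statistics.

Score-based classifiers (perceptron, ridge, SGD) emit decision scores,
not posteriors. The probability rule converts scores to a simplex
vector: `softmax` (default) or `onehot` hard routing. For classifiers
with native posteriors, `softmax` is applied on the log scale so it
reduces to renormalization rather than flattening the distribution. A
strict hard-routing mode matches the simplified mixture formula that
holds when the first stage is nearly always right; softmax is the
default because it preserves calibrated mixing of borderline samples.

Model selection is supported by `select_classifier()`: stratified k-fold
cross-validation (default 5-fold on the 70% training partition), ranking
candidates by mean weighted F1 across folds, descending, ties broken by
candidate order. Weighted F1 is used because support-weighted F1 is the
headline aggregate of this kind of imbalanced multiclass evaluation;
macro F1 and accuracy are also computed everywhere.

## Class imbalance: borderline-SMOTE

Imbalanced nodes are rebalanced by borderline-SMOTE. For each
non-majority class (one-vs-rest, all other classes pooled as majority,
classes processed in ascending label order):

1. For each minority sample, find its k nearest neighbors by Euclidean
   distance among **all** other samples and count majority neighbors
   m_i. Samples with k/2 ≤ m_i < k are *danger* points (near the
   boundary); m_i = k is *noise*, m_i < k/2 is *safe* — only danger
   points seed synthesis. The k/2 bound is real-valued: k = 5 puts
   m_i ∈ {3, 4} in the danger region.
2. Each synthetic row is x_new = x_i + λ(x_z − x_i) with λ ~ U[0, 1],
   x_i a danger seed and x_z drawn uniformly from x_i's k nearest
   *minority-class* neighbors, until the class reaches the majority
   count.

Decisions worth recording:

- **k defaults to 5** (the common reference default) and is exposed as
  `smote_k`.
- **Partner pool**: minority-class neighbors (the classic
  borderline-SMOTE-1 semantics); `neighbor_pool = "all"` is available.
- **Target size**: parity with the majority class — "rebalanced" is read
  as equal counts.
- **Placement**: oversampling is applied *inside* each node's training
  data, and in cross-validation *inside the training folds only*.
  Synthetic points never enter a validation or test partition; anything
  else would leak the oversampler into the evaluation.
- **Fallbacks**: a class with no danger points (fully safe or fully
  noise) is left unaugmented with a warning rather than synthesized from
  unsafe seeds.
- **Auditability**: every synthetic row's seed index, partner index and
  λ are logged, so tests verify each row is exactly the stated affine
  combination.

## Permutation importance and cross-disease stacking

The importance of feature i is the expected drop of a test-set score
when column i is randomly permuted, averaged over `n_perm` random
permutations (default 1000, matching the procedure's printed
approximation of the infeasible average over all n! orderings; an
`exact` mode enumerates all orderings for test sets of ≤ 7 samples and
is used as the oracle in tests). The score function defaults to weighted
F1 and is configurable (accuracy, macro F1, per-class one-vs-rest F1);
a constant column has importance exactly 0.

`stacked_importance()` evaluates each permutation once and scores it
against every disease's one-vs-rest F1, so per-disease contributions
cost one model evaluation per permutation. A protein's *occurrence* is
the number of diseases with strictly positive mean contribution (no
threshold beyond positivity is applied), and its *stacked score* is the
sum of positive contributions. Proteins are ranked by occurrence, ties
by stacked score, then column order — one consistent reading of
combining the "how many diseases" and "how strongly" perspectives into a
single ranking. `top_k()` feeds `restrict_to_features()`, which refits
the identical architecture on a protein subset (e.g. a top-100 panel).

## Evaluation and statistics

- `classification_report()` computes per-class precision, recall, F1
  (0 when undefined), supports, the confusion matrix, accuracy, macro
  and weighted F1. Structural identities (row sums = supports, accuracy
  = support-weighted recall) are tested.
- `auroc()` uses the Mann-Whitney identity with midrank tie handling.
  Multiclass AUROC is deliberately absent: ROC evaluation is performed
  on *binary restrictions* only — two entries of the multiclass
  posterior renormalized to sum to one (`restrict_binary()`), with no
  retraining. A row with zero mass on both classes becomes (0.5, 0.5)
  with a warning.
- `delong_test()` implements the structural-components (placement-value)
  covariance estimator for the variance of a difference of correlated
  AUCs, with a two-sided normal p. Conventions for degenerate inputs:
  zero variance with zero difference gives p = 1; zero variance with a
  nonzero difference is an error. The test suite cross-checks z and p
  against an independent implementation and the variance against a
  stratified paired bootstrap.
- `welch_protein_tests()` runs per-protein two-sided t tests
  (unequal-variance Welch by default; the pooled-variance variant is a
  flag, since either reading of "t test" is defensible), Bonferroni
  correction p_corrected = min(1, p × n) with n the panel size, and two
  standardized effect sizes: Cohen's d with pooled SD (primary; no
  formula is canonical so the convention is stated) and the
  Welch-denominator variant √((s₁²+s₂²)/2). Stars follow the panel-wide
  convention p < 0.01/n and p < 0.0001/n.
- `mann_whitney_test()` enumerates the exact permutation distribution of
  U (midrank ties supported) whenever min(n₁, n₂) ≤ 8 — small per-class
  metric vectors are exactly where the normal approximation is worst and
  ties are common — and otherwise uses the normal approximation with tie
  and continuity correction. `strata_performance_compare()` applies it
  to per-class precision/recall/F1 vectors of two test strata (sex, age
  or BMI groups; sex-specific phenotypes are excluded by the caller);
  the α = 0.01 decision is left to the caller.
- `sensitivity_analysis()` fixes one stratified split, fits a reference
  model, then repeatedly removes `round(removal_fraction × n_target)` of
  the target class's training samples (default one quarter), retrains
  with unchanged hyperparameters, evaluates on the fixed test partition,
  and compares each disease's target-vs-disease binary-restriction
  scores to the reference model's with the DeLong test.

## The synthetic cohort generator

Individual-level multi-disease NPX cohorts are access-restricted, so the
generator is the package's test bed. It emulates the *structure* such a
cohort presents to a classifier:

- **Baseline 0 for every protein.** NPX is a relative log2 scale; only
  shifts matter for classification, so means are modeled as shifts from
  an arbitrary zero.
- **Hierarchical mean structure**: category-level marker shifts shared
  by all diseases of a category, plus weaker disease-level shifts —
  the signal geometry that motivates a hierarchy.
- **Class imbalance as explicit per-class counts** (`n_per_class`),
  matching how such cohorts are described (per-disease n's), rather than
  a prevalence parameter.
- **Independent Gaussian noise** (`noise_sd`, NPX units). The
  between-protein covariance of real NPX panels is not characterized
  here; independence is the default and a correlation hook is left out
  deliberately rather than inventing a structure.
- **Optional demographic covariates** (sex, age, BMI) linearly coupled
  to chosen proteins, with an optional threshold nonlinearity —
  NPX-covariate relationships in real cohorts are typically nonlinear.
  Off by default.

What it does **not** emulate: assay mechanics (LOD, plate effects,
probe cross-reactivity), missingness, batch structure, heavy-tailed or
protein-correlated noise. Passing tests therefore demonstrate that the
algorithms behave as specified on data with planted hierarchical
structure — not that any particular performance level transfers to real
patient cohorts.

Study-shaped fixtures in the test suite use a 24-phenotype taxonomy
(4 + 2 + 5 + 12 diseases plus terminal healthy) with per-class counts
scaled down roughly tenfold from the cohort sizes typical of such
studies (5–31 per disease, 14 healthy, ~390 samples) over 200 proteins;
marker-recovery fixtures use 5 classes × 50–150 proteins with 30
permutations per feature. These sizes are the package's chosen desk
scale: large enough for the qualitative properties (hierarchy advantage
over a flat multiclass logistic baseline; recovery of planted markers in
the importance top-k; stability under healthy subsampling) to be
reproducible, small enough to iterate on.

## Numerical choices and conventions

- **Splits**: stratified, `ceiling(fraction × n)` training samples per
  class — a 137-sample class at 70% yields 96 training samples.
- **Tie-breaks**: fixed label order = order of appearance in the
  taxonomy (categories in file order, members in listed order, then
  terminals); argmax ties resolve to the earliest label. k-NN distance
  ties resolve by ascending sample index.
- **Label ordering inside nodes** uses radix (C-collation) sorting, so
  fits are byte-identical across locales.
- **Determinism**: every stochastic step (simulation, splits,
  oversampling, perceptron/SGD shuffling, tree seeds, permutations)
  derives from an explicit seed; the global RNG stream is saved and
  restored around all internal draws.
- **Missing NPX**: rejected for training; per-protein median imputation
  is available for prediction-only use.
- **Candidate family**: seven algorithms ship (logistic, ridge,
  perceptron, SGD, extra-trees, random forest, class-prior dummy) —
  the five used by the default design plus two useful comparators. The
  `node_spec` interface accommodates further classical classifiers, but
  only these seven are implemented and tested.

## Limitations

- Second-stage posteriors are evaluated unconditionally on x (see the
  mixture reading above); no calibration beyond softmax/one-hot is
  performed.
- The generator's independence assumption makes planted markers easier
  to recover than correlated real panels would be.
- Perceptron and SGD nodes are sensitive to epoch counts on tiny
  classes; defaults (50 and 20 epochs) suit cohorts of tens to hundreds
  of samples per node.
- The CLI persists models with R serialization inside the model
  directory; the JSON metadata is for humans and tooling, not a portable
  model format.
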