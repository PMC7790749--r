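---
title: "Methods: disease-specific pathogenicity classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: disease-specific pathogenicity classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathboost)
library(dplyr)
```

## The problem

Most rare missense variants in genes for monogenic diseases such as the
inherited cardiomyopathies and arrhythmia syndromes cannot be confidently
interpreted: genome-wide pathogenicity scores are trained across all genes
and diseases, and their scores for any one condition cluster in an
uninformative middle range. `pathboost` implements the disease-specific
alternative end to end: curate a gene-panel-restricted gold standard of
rare (population minor allele frequency < 0.1%) missense variants, train a
boosted-tree classifier on a fixed panel of functional annotations, report
a *probability of pathogenicity* Pr per variant, and evaluate everything at
the clinically meaningful thresholds Pr ≥ 0.9 (disease-causing) and
Pr ≤ 0.1 (benign), mirroring the ≥90% certainty implied by ACMG/AMP
likely-pathogenic / likely-benign categories. Variants in between are
clinically indeterminate. Downstream, predicted classes are validated
without recourse to the training labels: by case–control odds-ratio
enrichment per gene, and by survival stratification of variant carriers.

Because curated clinical variant sets cannot be redistributed, the package
ships seeded generators for all three input kinds (labelled feature
tables, per-gene carrier counts, per-patient survival records) with known
ground truth; every analysis here runs on simulated data.

## Data curation rules

* **Labels.** Clinical assertion sets are resolved by
  `curate_label()`: a variant is *pathogenic* only if all assertions are
  P/LP, *benign* only if all are B/LB, and *excluded* otherwise — any
  P/LP-vs-B/LB or VUS involvement is a conflict. The rule is a function of
  the assertion set only (order and multiplicity are irrelevant).
* **Rarity.** `filter_rare()` keeps variants with MAF strictly below the
  cutoff (default 0.001, i.e. 0.1%; 0.0001 gives an ultrarare filter).
  Variants *absent* from the reference population are kept: a large
  fraction of disease-cohort variants are unseen in population controls,
  and dropping them would discard exactly the variants the classifier is
  most needed for.
* **Splitting.** `split_train_test()` allocates two thirds to training,
  stratified by class with per-class ceiling allocation (the fractional
  remainder goes to training), so each class's training share deviates
  from the target by at most one variant. The split is a pure function of
  the seed.

## The classifier

`fit_adaboost()` implements discrete AdaBoost over depth-limited decision
trees, written in full here because the per-round quantities are part of
the model contract. With labels y ∈ {0, 1} (pathogenic = 1) and uniform
initial weights, round *m*:

1. fits a depth-`tree_depth` tree to the weighted sample (weighted Gini
   splits, weighted-majority leaf votes);
2. computes the weighted misclassification error ε_m;
3. sets the round weight α_m = ½·log((1 − ε_m)/ε_m);
4. multiplies misclassified sample weights by exp(2 α_m) — the standard
   exponential-loss update — and renormalises.

Boosting stops early when ε_m = 0 (the round is kept with α capped at
`alpha_cap`, default log(10⁶)) or when ε_m ≥ ½ (the round is discarded; if
this happens in round one no valid model exists and fitting aborts).
Missing feature values are imputed by the training median, which is stored
in the model and reused at prediction time, so a saved model is
self-contained. Models serialize to versioned JSON at full double
precision (`save_model()` / `load_model()`); a reloaded model predicts
bitwise-identically, and the suite asserts this.

**Defaults.** `n_rounds = 500`, `tree_depth = 3`. Five hundred rounds of
depth-3 trees is a conventional operating point for boosted ensembles on
feature tables of this width; both are configurable and the selection
machinery tunes them where that matters.

### The probability transform

Two transforms of the ensemble's weighted votes are implemented
(`predict_pr(..., transform = )`); choosing the default was the one
genuinely open design decision in this module.

* `"logistic_margin"` (default): Pr = σ(2F) with the signed margin
  F = Σ_m α_m (2 h_m − 1), the classical exponential-loss probability
  estimate for AdaBoost (Friedman, Hastie & Tibshirani 2000).
* `"vote_share"`: the normalised weighted vote Σ α_m h_m / Σ α_m.

The vote share looks natural but is unusable for three-way clinical
calling, for a structural reason: boosting makes its trees disagree on
purpose (each round concentrates on the previous rounds' mistakes), so
even on perfectly separable data the vote share crowds into roughly
(0.3, 0.7) and essentially never reaches the 0.9/0.1 bands — and adding
rounds makes this *worse*, since later trees dissent more. Measured on
separable simulated data (aggregate separation d = 4, 500 + 500 variants,
500 rounds) the proportion of high-confidence calls under the vote share
is exactly zero, while the logistic margin reproduces the intended bimodal
score distribution. Both transforms are monotone in every tree's vote and
agree on which side of 0.5 a variant falls; the vote share is retained for
diagnostics and its arithmetic is pinned by tests.

The logistic margin is deliberately *not* recalibrated (no Platt scaling /
isotonic step): Pr is a monotone transform of the boosting margin, and the
three-way thresholds act on it directly. On hard data it is overconfident
in the usual boosted-margin way, which inflates the proportion of
high-confidence calls relative to a calibrated probability; the Brier
score in the evaluation suite is the place this shows up.

## Model selection

`nested_select()` runs the two-loop cross-validation: an inner
`inner_k`-fold loop (default 5) tunes each candidate's hyperparameter grid
on the outer-training part only, and an outer `outer_k`-fold loop (default
10) scores the tuned candidates on held-out folds; the winner maximises
the mean outer metric. The selection metric defaults to PR-AUC, the right
first metric for class-imbalanced variant panels; ROC-AUC and negative
Brier are available. Determinism and honesty rules, all covered by tests:
fold assignments are stratified (per-fold class counts within one of
balance) and seeded; every tie — grid points, algorithms — is broken by
first-in-order position; a candidate that fails to fit scores −Inf rather
than aborting the loop; outer-fold rows are provably invisible to the
inner loop (an instrumented candidate records every training set it sees).

The default registry (`default_registry()`) holds nine candidates spanning
the major algorithm families — boosted trees (this package's model),
gradient boosting, random forest, L1 logistic regression, RBF-kernel SVM,
k-nearest-neighbour, naive Bayes, a single decision tree, and a small
feed-forward net — the latter eight wrapping standard implementations
(xgboost, ranger, glmnet, e1071, class, rpart, nnet) with small default
grids. They are comparison stand-ins: only the boosted-tree candidate's
behaviour is specified and guaranteed by this package.

## The clinical metric suite

`confusion_summary()` derives every thresholded quantity from one set of
labels, probabilities and thresholds. Conventions that matter:

* TPR and TNR keep the full class sizes in their denominators — an
  indeterminate pathogenic variant counts *against* sensitivity. PPV and
  NPV condition on high-confidence calls only.
* Two identities hold by construction on every input and are asserted on
  randomized inputs: overall accuracy = (proportion classified with high
  confidence) × (accuracy of high-confidence calls), and proportion
  indeterminate = 1 − proportion high confidence.
* Zero-denominator rates are `NA` ("undefined-flagged"), never a silent 0
  — small subgroup analyses would otherwise fabricate perfect rates.
* Rounding of reported percentages (half-up, one decimal;
  `round_half_up()`) is a reporting-layer operation only.

Threshold-free metrics: `roc_auc()` is the Mann–Whitney pair-counting
form (ties count one half; equal to a brute-force pairwise oracle on every
tested instance); `pr_auc()` is the average-precision step form with tied
scores processed as one block — no trapezoidal interpolation, which is
optimistic on PR curves; `brier()` is the mean squared probability error.

Classifier comparisons: `paired_permutation_test()` swaps the two
classifiers' probabilities per variant (a paired design), enumerating all
2ⁿ swap patterns exactly when n ≤ 12 and otherwise using seeded
Monte-Carlo with the add-one correction (b + 1)/(n_perm + 1);
`delong_test()` compares correlated ROC-AUCs (via pROC's paired DeLong
implementation) with the zero-variance edge cases defined: identical
scores give p = 1. `predictive_values_at_prevalence()` projects the
measured high-confidence call rates onto a population with a different
prior via Bayes' rule — the remainders left by indeterminate calls drop
out of both predictive values. `evaluate_subgroups()` applies the full
suite to two index-defined subsets (e.g. variants seen vs unseen by an
upstream resource) with a permutation p-value for the accuracy
difference.

## Cohort-level validation

* `gene_odds_ratio()`: carrier-based cross-product odds ratio with the
  Woolf log-normal confidence interval; any zero cell triggers the
  Haldane–Anscombe +0.5 correction on all four cells of that table, and
  the row is flagged. Carriers are counted once per gene per cohort.
* `stratified_or_comparison()`: per-stratum ORs (all rare variants /
  predicted disease-causing / predicted benign) with a two-sided z-test on
  the log-OR difference from the all-rare baseline, variance the sum of
  the two Woolf variances. The independence approximation is conservative
  because the strata share cohorts; the output documents this limitation.
* `km_estimate()` / `logrank_test()` / `cox_hr()` are thin, contract-
  checked surfaces over the survival package (`survfit`, `survdiff`,
  `coxph` with Breslow tie handling); the tests pin them to hand-computed
  product-limit and hypergeometric oracles. Monotone likelihoods (a group
  without events) come back flagged, not as crashes.
* `outcome_risk_by_age()`: difference in cumulative incidence at an age
  (default use: age 60) with a percentile bootstrap CI, patients resampled
  within group; `n_boot` defaults to 2000.

## What the generators emulate — and what they do not

`feature_gen_spec()` defaults describe one curated condition panel:
356 pathogenic and 302 benign variants across 16 genes, 76 annotation
features (half Beta-distributed unit scores, half Gaussian continuous
annotations), 5% missing cells, and 45% of variants absent from the
population reference, all below the 0.1% rarity cutoff.

The `separation` parameter is the *aggregate* effect size: the per-feature
class shift is d/√p (logit scale for unit scores, SD units for continuous
features), so difficulty is governed by d independent of schema width;
d = 0 is an exchangeable null. The default d = 2 was chosen once so that
holdout discrimination lands where disease-specific classifiers on real
panels land (ROC-AUC around 0.9, as `scripts/acceptance.R` recomputes)
rather than at a trivially separable extreme.

`cohort_gen_spec()` defaults: 6327 cases vs 138,632 reference samples,
eight genes, carrier frequency 0.002, and three strata per gene with true
ORs 5 (all rare), 15 (predicted disease-causing) and 1 (predicted benign).
`survival_gen_spec()` defaults: three groups of 2000 patients with hazard
ratios 1 (genotype-negative reference), 1.12 (predicted benign) and 1.9
(predicted disease-causing), exponential event ages with the baseline rate
solved so the reference group reaches 33% cumulative incidence by age 60,
and uniform censoring between 40 and 80 years. The 1.9/1.12 pair makes
the disease-causing-vs-benign contrast ≈1.7.

What the generators deliberately do not model: inter-feature correlation
(real annotation panels are strongly collinear), annotation-specific score
distributions, gene-level effect heterogeneity within a stratum,
non-proportional hazards, and competing risks. Passing tests therefore
demonstrate that the *machinery* is correct and recovers known parameters
at realistic sizes — not that a retrained model has clinical validity on
any real panel.

## Numerical choices and degenerate inputs

* Tree splits consider only positions where consecutive sorted feature
  values differ; thresholds are midpoints; a node with no
  impurity-reducing split becomes a leaf. Leaf ties vote pathogenic
  (weighted class probability exactly ½), a fixed deterministic rule.
* ε comparisons use a 10⁻¹² guard: ε ≥ ½ − 10⁻¹² stops, ε < 10⁻¹² is
  treated as a perfect round.
* All-constant feature matrices fit (with a warning) but typically abort
  as no-better-than-chance in round one.
* Model JSON is written with 17 significant digits so doubles round-trip
  exactly.
* Every seeded routine derives sub-seeds deterministically from its master
  seed; reports are byte-identical across runs with equal seeds.

## Problem sizes in the test suite

The suite exercises each component at the smallest size that makes the
check meaningful: metric oracles at n ≤ 50 with exhaustive enumeration at
n ≤ 12; parameter recovery at the cohort scale it claims (2000 patients
per group for the hazard ratio of 1.9; 100 interval-coverage replicates;
200 null replicates for log-rank size); and the nested-selection run at
500 + 500 variants with the full outer-10/inner-5 design. The complete
suite runs in a few minutes on one CPU.

## Limitations

This package retrains from whatever labelled table it is given; it ships
no trained weights, no genome-wide precomputed scores, and no annotation
retrieval (inputs must already carry their features). The placeholder
76-column schema mirrors a realistic panel's shape, not its content.
Probabilities are uncalibrated boosted margins (see above). The
stratified-OR test is conservative by construction, and survival analyses
assume proportional hazards with a single composite endpoint per patient.
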