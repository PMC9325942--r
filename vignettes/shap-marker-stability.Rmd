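---
title: "Reliability and stability of Shapley markers across the cognitive spectrum"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reliability and stability of Shapley markers across the cognitive spectrum}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Local attribution methods (SHAP and relatives) attach to every model
prediction a vector of per-feature contributions. In a clinical setting these
vectors are tempting to read as *markers*: if the model classifies a patient's
cognitive status from ten neuropsychological indexes, the attribution vector
says which cognitive domains drove that call. But a marker is only useful if
it is reliable — similar patients should receive similar explanations — and if
its changes over time track something real. `cogshap` implements a complete
framework for interrogating both questions in a three-class classification of
cognitive status (normal controls NC, mild cognitive impairment MCI,
Alzheimer's dementia AD) from ten indexes: ADAS11, ADAS13, MMSE, MoCA, FAQ,
three RAVLT subscores, and the two Everyday Cognition totals (participant- and
study-partner-rated).

The pipeline has five stages, each usable on its own:

1. **Synthetic cohort** (`generate_cohort`): longitudinal subject-visit tables
   with class-conditional Gaussian index distributions and stable/converter
   trajectories.
2. **Classification** (`classify_cohort`): a random-forest ensemble with
   class-balanced undersampling, subject-level cross-validation, nested
   hyperparameter search, and probability averaging.
3. **Attribution** (`explain_cohort`, `exact_shapley`, `monte_carlo_shapley`):
   exact Shapley values by full coalition enumeration, averaged over the
   ensemble.
4. **Cross-sectional analysis** (`cross_sectional_analysis`): cosine-distance
   similarity networks of attribution vectors within the true-by-predicted
   categories, ANOVA with post-hoc comparisons, bootstrap k-medoid cluster
   stability, per-cluster feature tests.
5. **Longitudinal analysis** (`longitudinal_analysis`): first-versus-last-visit
   attribution distances per subject, trajectory classes, ANCOVA with
   demographic covariates, and permutation tests.

`run_full()` chains all five under one configuration and one seed.

## The synthetic cohort: a stated world

The framework was designed against a restricted-access longitudinal ageing
cohort; the generator reproduces the *published* statistical structure of that
cohort so the pipeline is testable end to end without the data. Its defaults
are the published per-class means and standard deviations of the ten indexes,
of age and education, and the per-class male proportions
(`default_class_params()`). Choices the published tables do not determine were
fixed once:

- **Independence across indexes.** The publication reports marginal
  means/SDs only, so indexes are drawn independently per class. A user-supplied
  correlation matrix (Gaussian copula) is accepted for sensitivity analyses.
  Consequence: the synthetic classes are *at least as separable* as the real,
  strongly correlated data — which is exactly why the classifier bounds in the
  acceptance suite are one-sided (`>=`).
- **Clipping.** Gaussian draws are clipped to instrument ranges (MMSE and
  MoCA 0–30, FAQ 0–30, ADAS11 0–70, ADAS13 0–85, RAVLT-immediate 0–75,
  RAVLT-learning −15–15, RAVLT-percent-forgetting −100–100, Ecog totals 1–4),
  because the published SDs otherwise generate impossible scores. Clipping
  censors the marginals: indexes whose class mean sits within about one SD of
  a bound (NC FAQ, NC/MCI Ecog, NC MMSE, AD RAVLT-percent-forgetting) have
  sample means visibly shifted from the nominal parameter. `clip = FALSE`
  recovers the pure Gaussian sampler; the test suite checks moment convergence
  on the unclipped sampler and range validity on the clipped one.
- **Within-subject dynamics.** The publication says nothing about
  within-subject temporal autocorrelation. Converters switch their diagnostic
  label at the midpoint visit (`switch_visit`, configurable); with
  `drift = "linear"` the index means and SDs interpolate linearly from the
  start-class to the end-class parameters across visits, with `"step"` they
  jump at the switch. Stable subjects redraw independently at each visit.
  This is a stand-in, not a claim about real cohort dynamics: it produces the
  qualitative structure the longitudinal stage needs (converters' profiles
  move, stables' do not), nothing finer.
- **Demographics.** Age and education are Gaussian per class (age clipped to
  the cohort's 55–90 recruitment range, advancing 0.5 years per visit); sex is
  Bernoulli with the per-class male proportion. They exist to serve as ANCOVA
  covariates.

A green test on this world therefore establishes that the *machinery* is
correct and that the qualitative orderings the framework is meant to detect
are detectable; it does not certify performance numbers on real cohort data,
where correlated indexes, missingness and drop-out make every class boundary
harder.

## The classification stage

Class imbalance (dementia is the smallest class) and repeated measures (every
subject contributes several visits) both bias a naive fit. The ensemble
handles them the way the reference protocol does:

- **Subject-level CV.** `cv = "loso"` holds out all visits of one subject per
  round (the reference protocol); `cv = "grouped-kfold"` is the desk-scale
  alternative, partitioning subjects (stratified by baseline diagnosis) into
  `n_folds` folds. No subject ever appears on both sides of a split.
- **Undersampling ensemble.** Per CV round the training pool is undersampled
  `U` times to `n_train` rows per class; each balanced draw is refit; the
  held-out visits get `U` probability triples whose mean is the reported
  probability. Final label = argmax with the fixed tie-break NC < MCI < AD.
  Reference scale is `U = 100`, `n_train = 500`; `run_config()` defaults to
  the desk scale `U = 10`, `n_train = 100` with a `paper_scale` switch.
- **Nested tuning.** Inside each balanced draw, `(ntree, mtry)` is selected
  from the grid by stratified `inner_k = 3`-fold CV maximizing multiclass
  accuracy (the selection metric was not published; plain accuracy is the
  simplest defensible choice), then refit on the full draw.
- **The forest itself** is a standard CART random forest (Gini impurity,
  bootstrap per tree, `mtry` candidate features per split, leaf class
  proportions averaged across trees), implemented in C++ inside the package
  because the target environment ships no tree learner. It is fully
  deterministic given its seed, including across compilers (it uses its own
  xorshift generator rather than `std::` distributions).

**Metrics.** Per class, one-vs-rest accuracy, sensitivity, specificity and
precision, plus an unweighted macro "Global" row, and one-vs-rest AUROC
computed as the normalized Mann–Whitney statistic (midranks for ties). The
published formula sheet prints specificity with the accuracy formula — an
evident typo, since the accompanying results table reports distinct accuracy
and specificity values — so the standard TN/(TN+FP) is computed;
`compute_metrics(spec_as_printed = TRUE)` reproduces the printed formula.
Ratios with zero denominator are reported `NA`, never 0. How the original
"Global" row was aggregated (macro vs support-weighted) is unstated; macro is
used and labelled as such.

## The attribution stage

With S = 10 features exact Shapley values are cheap: all `2^10 = 1024`
coalition values are evaluated in one pass. The value function is the
*interventional* expectation: `v(F)` is the mean model score over a background
set in which the coalition's features are fixed to the explained sample and
the rest keep their background values. The background is a class-balanced
subsample (default at most 100 rows) of the same CV round's training pool, so
explanation — like prediction — never sees the explained subject's data.
Design points:

- **What is explained.** By default the probability of the sample's final
  (ensemble-averaged) label; `target` can fix any single class instead. The
  original study does not state which score it explained.
- **Ensemble averaging.** One attribution vector per ensemble member, then the
  arithmetic mean across the `U` members (mirroring the probability
  averaging); baseline and explained prediction average identically, so local
  accuracy — baseline + sum of attributions = explained prediction — survives
  averaging by linearity. Whether the original computed SHAP per retraining or
  on one refit model is unstated; both orderings are linear operations over
  the same quantities.
- **Monte Carlo estimator.** For wider feature sets,
  `monte_carlo_shapley()` averages marginal contributions over sampled feature
  orderings (unbiased), then redistributes the residual efficiency gap equally
  across features so that downstream cosine analyses always operate on
  efficiency-consistent vectors. The enumeration cap (default 15 features)
  marks where exact enumeration stops being desk-feasible.
- **Verification.** The test suite checks exact enumeration against an
  independent brute-force average over all S! orderings (S ≤ 6), the
  closed form `phi_j = w_j (x_j − mu_j)` for linear scorers, the dummy and
  symmetry axioms, and a `1e-9` local-accuracy bound for every explained
  sample in pipeline runs.

## Cross-sectional analysis

Samples are grouped by true-by-predicted category (NC-NC, NC-MCI, MCI-NC,
MCI-MCI, MCI-AD, AD-MCI, AD-AD; the two extreme cross pairs NC-AD/AD-NC are
excluded as vanishingly rare). Within each category all pairwise cosine
distances between attribution vectors form the category's similarity network;
categories are compared by one-way ANOVA over these distance collections with
Tukey HSD post-hoc (pairwise Welch t-tests with Holm correction as the
configurable alternative — the original states only "post-hoc comparisons").
Two honest caveats are documented rather than hidden:

- Pairwise distances sharing a sample are not independent; the ANOVA treats
  them as observations anyway (as the original's group sizes imply). Treat the
  p-values as descriptive.
- A zero-norm attribution vector has no direction; its cosine distance to
  anything is defined as 1 (orthogonality) with a warning, keeping the
  operation total.

**Cluster stability.** Each network is partitioned by k-medoids (PAM via
`cluster::pam`) for k in 1..20, and each partition's credibility is measured
by bootstrap clusterwise stability: resample members with replacement,
re-cluster the resample (duplicates included), classify every original member
to its nearest bootstrap medoid, and record each original cluster's best
Jaccard match; a cluster's stability is its mean Jaccard over `B = 100`
bootstraps. Two implementation decisions deserve emphasis because the obvious
alternatives fail:

- *Cluster the multiset, not the deduplicated resample.* Deduplicating first
  reduces the bootstrap to a mild ~0.63 subsample whose clustering is nearly
  identical to the original — stability is then inflated to the point where
  an isotropic Gaussian blob shows "stable" 2–5-way splits. The
  classification-based convention (that of the reference implementation of
  this criterion) keeps the perturbation honest.
- *Select k by stability, not by counting stable clusters.* On strongly
  separated data, halves of a true cluster can individually clear the 0.75
  threshold, so "maximize the number of stable clusters" over-partitions.
  The rule used: among k ≥ 2 whose *minimum* per-cluster stability reaches
  0.75, take the k with the highest minimum (ties: higher mean, then smaller
  k); if none qualifies, k = 1. On planted two-cluster data (10 SD apart,
  n = 50) this selects k = 2 with stability 1.0; on a single 10-dimensional
  Gaussian blob no k ≥ 2 reaches 0.75.

Clusters found this way are characterized on the *original* index values:
Student's t-test per index for two clusters, one-way ANOVA (or
Kruskal–Wallis) for more, with per-cluster means ± SD reported.

## Longitudinal analysis

Subjects with at least three visits contribute their first and last
attribution vectors; the subject's longitudinal change is the cosine distance
between them. Subjects are classed as stable NC/MCI/AD or NC→MCI, NC→AD,
MCI→AD converters; diagnostic reversions (not addressed by the original
protocol) are labelled OTHER and excluded. Distances are compared across
classes by ANCOVA (`distance ~ class + age + sex + education`, covariates at
first visit; class effect by F-test of the nested models; post-hoc by
studentized-range comparisons of covariate-adjusted means).

Two permutation tests, whose null schemes the original leaves unstated, are
defined as follows and calibrated in the test suite:

- **Class-level test.** Observed: mean within-subject first-last distance.
  Null: last-visit vectors randomly re-paired across subjects within the
  class. Within-subject first/last swaps would leave the *symmetric* cosine
  distance invariant — a degenerate null — hence the cross-subject re-pairing.
  One-sided toward large distances by default (`alternative` configurable);
  p = (r + 1)/(B + 1) with r = #(null ≥ observed), B = 1000 by default.
- **Per-index test.** Observed: |mean over subjects of (last − first)
  attribution of index j|. Null: independent per-subject first/last swaps,
  i.e. sign flips of each subject's difference — exact for symmetric
  difference distributions. Same p-value formula; the smallest attainable p
  is 1/(B+1).

Both tests hold empirical type-I error within [0.03, 0.07] at the 0.05 level
over 500 null replicates in the acceptance suite. Per-class mean first/last
attribution profiles are tabulated (`radar` output) with signed means;
absolute-value averaging is a one-liner on the records table if preferred —
the original figure does not say which it shows.

## Numerical and interface choices

- One global seed drives everything; stage seeds are derived deterministically
  (`stage_seed`), and every stochastic function takes an explicit seed.
  Identical configuration + seed reproduces every output byte-identically.
- Argmax ties break by the fixed class order NC < MCI < AD; grid-search ties
  break toward the earlier grid point (smaller `ntree`, then `mtry`).
- Degenerate statistical inputs return conventional values rather than
  erroring mid-pipeline: all-equal groups give p = 1; zero-norm vectors give
  cosine distance 1 with a warning; undefined metric ratios give `NA`.
- `k = n` medoids (every point its own medoid, cost 0) is handled directly
  since PAM proper requires k < n.
- The pipeline writes plain CSV/JSON only; plots are intentionally out of
  scope (the analyses are the product; figures are conveniences).

## Limitations

- The synthetic world omits index correlations, missing data, practice
  effects and irregular visit spacing; all were present in the original
  cohort. Absolute performance numbers on synthetic data are upper bounds.
- Exact Shapley cost grows as `2^S x |background| x U`; beyond ~15 features
  use the Monte Carlo estimator.
- ANOVA on pairwise distances ignores pair dependence (documented above).
- The stability criterion measures reproducibility under resampling, not
  cluster validity; a stable split is not automatically a clinically
  meaningful one.
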