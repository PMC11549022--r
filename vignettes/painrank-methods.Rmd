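---
title: "Methods: imbalance-aware pain-gene prioritization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: imbalance-aware pain-gene prioritization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

Identifying genes involved in pain is limited less by data than by labels:
functional in-vivo validation is slow, so the set of confidently "pain"
genes is tiny (about one positive per forty negatives), and many of the
negatives are simply unstudied. `painrank` frames prioritization as binary
probabilistic classification over the whole gene universe. Each gene is
described by genomic annotations, ontology membership, differential
expression across tissues and species, and its position in a
protein–protein interaction (PPI) network; a weighted soft-voting ensemble
of tree learners emits a class-1 probability — the *pain score* — used to
rank all genes. The working assumptions are:

- **Guilt by association.** Disease genes tend to be network hubs and to
  sit near each other in the interactome, so centrality features (degree,
  stress, radiality, edge count) carry signal.
- **Functional coherence.** Positives share ontology terms; rare terms are
  more informative than ubiquitous ones, hence the prevalence filter and
  TF-IDF weighting.
- **Convergent dysregulation.** Across independent injury/pain omics
  datasets, positives are more likely to be significantly differentially
  expressed, though each dataset highlights a different subset.
- **Weak labels on the negative side.** A high score for a "non-pain" gene
  is a prediction, not an error; evaluation therefore uses
  imbalance-robust metrics and rank enrichment rather than accuracy.

## Evaluation metrics

From the 2×2 confusion matrix at probability threshold 0.5 (the package
default wherever hard labels are needed): Matthews correlation coefficient
(MCC), geometric mean of sensitivity and specificity (GM), F1, and balanced
accuracy (BA). Degenerate folds are kept defined by convention: a
sensitivity/specificity/precision with zero denominator counts as 0, MCC is
0 when any marginal factor of its denominator is 0, and F1 is 0 when
precision + recall = 0. Note that an always-wrong classifier (TP = TN = 0
with FP, FN > 0) has a *non*-degenerate denominator and MCC exactly −1.
Cross-validation reports per-fold metric sets plus their mean and SD over
folds (the SD is over folds, not repeated runs; per-fold values are kept so
either summary can be recomputed).

## Network topology features

Eleven per-node features of the undirected PPI graph. igraph supplies
shortest-path distances, normalized betweenness and the local clustering
coefficient; the remaining features follow the conventions of the widely
used network-analysis tooling this feature set originates from:

- *average shortest path, closeness, eccentricity, radiality* are computed
  within connected components ("noninfinite" convention); closeness is the
  reciprocal of the average shortest path; radiality of `v` is
  `Σ_w (Δ+1 − d(v,w)) / (n_c − 1)` with `Δ` the component diameter and
  `n_c` the component size; isolated nodes score 0.
- *stress* counts shortest paths through a node, endpoints excluded, each
  unordered source–target pair once. It is computed by a Brandes-style
  accumulation in C++ (`src/stress.cpp`): per BFS source `s`,
  `σ_s(v)·φ_s(v)` counts shortest paths from `s` through `v`, where `φ` is
  the descendant path count in the shortest-path DAG; summing over sources
  counts each unordered pair twice.
- *topological coefficient* of `v` averages `J(v,w)/deg(v)` over nodes `w`
  sharing at least one neighbour with `v`, where `J` is the shared-neighbour
  count plus 1 if `v,w` are adjacent; nodes of degree < 2 score 0.

Tests verify all eleven features against a brute-force oracle that
explicitly enumerates every shortest path on random 6–12-node graphs.
STRING-style edge scores are respected through an optional `min_score`
filter; the confidence cutoff is deliberately a caller decision.

## Feature engineering choices

- **Ordinal encoding** assigns integer codes in sorted label order
  (deterministic across runs); labels unseen at fit time get a reserved
  code.
- **GO features.** Terms whose *name* contains "pain" (case-insensitive)
  are excluded before anything else — the gold-standard labels are defined
  by pain involvement, so such terms are near-restatements of the label.
  Terms in ≥ 20% of genes are dropped (strictly-less-than retention).
  TF-IDF uses the smoothed IDF `ln((1+N)/(1+df)) + 1` with L2 row
  normalization; two principal components (`GO1`, `GO2`) are kept by
  default. Vocabulary, IDF and PCA are fitted on training genes only.
- **Composite LFC.** The phrase "non-significant entries" is taken at face
  value: entries with FDR ≥ 0.05 (or missing) are zeroed, then LFC columns
  are averaged per gene within each tissue × species group. Zeroed entries
  stay in the denominator, so a gene significant in one of two datasets
  gets half its effect — deliberate shrinkage towards reproducible effects.
- **Correlation filter.** "Highly correlative" pairs are those with
  |Pearson r| ≥ 0.75; the smaller-variance member is dropped (ties: the
  later column), iterating until no pair remains.
- **Scaling.** Min–max to [−1, 1], fitted on training rows and applied to
  all rows; validation values outside the training range legitimately fall
  outside [−1, 1]. Constant features map to 0. Missing numeric values are
  imputed as 0 (= no change / not detected) before scaling.
- **Split.** 70/30, stratified by label, seeded.

## Ensemble

The four voting members are tree ensembles trained with xgboost
(single-threaded, seeded, hence bit-reproducible):

| member | construction |
|---|---|
| `xgbm` | regularized gradient-boosted trees (depth 4, η 0.1, λ 1, row/column subsampling) |
| `gb`   | classic gradient boosting (λ = α = 0, no column subsampling, depth 3) |
| `ada`  | stagewise additive modeling with exponential loss on depth-1 stumps — the statistical formulation of adaptive boosting — via a custom objective; probabilities recovered as `1/(1+exp(−2f))` |
| `rf`   | random forest: one boosting round of 400 bagged trees with per-node feature subsampling |

A single engine was chosen so that every member yields exact tree-path
(TreeSHAP) attributions, which the weighted SHAP aggregation requires.
Class imbalance is handled by weighting positives by `N_neg/N_pos`
(`scale_pos_weight`; applied inside the custom objective for `ada`), which
keeps the 0.5 threshold meaningful at 1:40 imbalance.

**Voting weights** come from an exhaustive search over all 24 distinct
permutations of {4, 2, 1, 3}, scored by GM of the soft vote on
*out-of-fold* member probabilities (5 folds by default) — the training rows
themselves would reward overfit members. Ties break to the first
permutation in lexicographic order. The stacking variant fits a logistic
meta-model on the same out-of-fold probabilities.

**Feature selection.** Backward elimination drops one feature per step down
to one, re-evaluating the cross-validated objective each step; the dropped
feature is the one with the lowest mean absolute SHAP (`order = "shap"`,
default). Whether to drop by attribution rank or by leave-one-out refit is
genuinely open; the refit variant is available as `order = "refit"` at a
quadratic cost in model fits. The selected subset maximizes GM with MCC as
tie-break. Hyperparameter tuning is a pluggable, seeded random search over
caller-supplied ranges maximizing the summed GM + MCC + BA + F1.

## Rank validation

The ranking is validated by a running-sum enrichment statistic: walking the
ranking from the top, hits add `1/K`, misses subtract `1/(N−K)`; the
enrichment score (ES) is the signed extremum. The unweighted (exponent-0)
form is the default because the pain score's scale is irrelevant — only its
order matters; a score-weighted variant (exponent 1) is available. The null
permutes set membership over the ranked universe (there are no sample
phenotypes to permute), and p-values use the add-one estimator
`(1 + #{|ES*| ≥ |ES|})/(n_perm + 1)` (default 1000 permutations,
configurable) so p = 0 is impossible; ties count as at-least-as-extreme,
with a 1e−12 tolerance so exact rational ties are not split by floating
point. Exact ties between the positive and negative extremum resolve to the
positive branch.

**Leakage removal** subtracts all training-labelled positives from every
validation set before enrichment; both results are reported side by side. A
set that empties under removal is reported as unavailable rather than
silently skipped.

Decile over-representation uses the hypergeometric upper tail per
annotation term over the top (or bottom) ⌈10%⌉ of the ranking, BH-corrected
across terms, significance at adjusted p < 0.05.

## The synthetic cohort

`sim_config()` defaults define the emulated study: n = 4100 genes,
pos_fraction = 1/41 (exactly 100 positives), preferential-attachment graph
with 3 edges per node, positives sampled ∝ degree², 300 GO terms with
base prevalence U(0.01, 0.15) of which 30 are enriched in positives at
odds ×4, six tissue × species omics groups with two LFC/FDR dataset pairs
each, effect size 1 (log₂) on a random half of the positives per dataset
(emulating that different experiments highlight different genes), noise SD
1, 5% spuriously significant background, log-normal TPM, and an external
validation set of twice the positive count overlapping positives by 50%.
A decoy term named "response to pain signal", enriched in positives, is
always planted to exercise the exclusion guard. The master seed fans out to
per-component seeds by fixed offsets, so components are individually
reproducible. Gene identifiers are synthetic (`G000001`…) to avoid
accidental biological claims.

What the generator does *not* emulate: correlated expression across
tissues, ortholog structure between species, realistic GO term hierarchies,
and annotation biases of real databases. Passing tests therefore show the
pipeline recovers the *kind* of structure the method assumes, at the
stated sizes — not that the method's real-data performance is reproduced.
On the synthetic defaults the planted signal is strong (held-out GM ≈ 0.95
versus ≈ 0.18 for a permuted-label null), whereas real labels are noisier
and real features weaker; the synthetic run is a correctness and
calibration check, not a performance claim.

## Numerical and operational choices

- Probability threshold 0.5 everywhere a confusion matrix is needed; the
  threshold is a parameter of `cross_validate()`.
- All stochastic components (learners, folds, tuner, permutations,
  simulators) take explicit seeds; the package default is 20240101, and
  `run_pipeline()` derives stage seeds from its master seed by fixed
  offsets, logging all of them.
- Learners run single-threaded so results are independent of thread count;
  two runs with the same configuration and seed produce byte-identical
  score tables and model cards.
- Test problem sizes: unit tests use cohorts of 250–800 genes; the
  end-to-end recovery checks run the full 4100-gene conditions across five
  seeds; topology oracles use 6–12-node graphs where exhaustive path
  enumeration is feasible; enrichment calibration uses 200 replicates of a
  150-gene universe at 400 permutations.
- The pipeline's two documented interpretation decisions (FDR ≥ 0.05 is
  "non-significant"; |r| ≥ 0.75 is "highly correlative") are written into
  every run log.

## Known limitations

- The full 58-feature inventory of a real study cannot be reconstructed
  name-by-name; the schema is configurable and the synthetic cohort's
  engineered space is ~24 features after zero-variance and correlation
  filtering.
- SHAP attributions are exact for the tree members but the stacking
  meta-model is explained only through its members' attributions.
- No probability calibration, ROC machinery, or normalized enrichment
  scores across set sizes; model selection rests on MCC/GM/F1/BA and raw
  ES, as designed.
- Ortholog mapping, live database retrieval (STRING, Ensembl) and web
  deployment are out of scope; inputs are plain TSV/YAML/GMT files.
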