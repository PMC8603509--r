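---
title: "Rare cell type annotation by LoRAS synthetic oversampling"
author: "scLoras"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rare cell type annotation by LoRAS synthetic oversampling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scLoras)
```

# The model

## Why oversample

A rare cell type with imbalance ratio $IR = n_{maj}/n_{min}$ in the
hundreds defeats standard classifiers: a k-nearest-neighbour vote over a
training set in which rare cells are 1 in 100 almost never reaches a
minority majority among its neighbors, and a logistic regression pays
almost no loss for ignoring the minority entirely. The symptom is a recall
near zero at high precision. Synthetic oversampling rebalances the
*training* data so that the classifier can learn the minority manifold,
while evaluation always happens on untouched held-out cells.

## LoRAS sample generation

LoRAS (Localized Random Affine Shadowsampling) builds synthetic minority
cells from small local neighborhoods rather than from global line segments
(the SMOTE family's construction). For each minority cell $p$ with
expression vector $x_p \in \mathbb{R}^d$:

1. **Neighborhood.** Find the $k$ nearest minority cells of $p$. When the
   minority class is large enough, neighborhoods are taken in a 2-D t-SNE
   embedding of the minority class, which better approximates the local
   data manifold; for very small minorities (default: below 50 cells) a
   2-D embedding is not meaningful and the raw feature space is used. The
   neighborhood is $\{p\} \cup \mathrm{kNN}(p)$, so it always contains
   $k + 1$ cells and generation stays anchored at $p$.
2. **Shadowsamples.** Each neighborhood cell is copied $n_{shadow}$ times
   and perturbed by independent per-feature Gaussian noise with standard
   deviations $L_\sigma \in \mathbb{R}^d_{\ge 0}$. Perturbed values are
   clipped at 0, since expression cannot be negative.
3. **Convex combination.** A synthetic cell is
   $\sum_{i=1}^{N_{aff}} w_i s_i$ where the $s_i$ are $N_{aff}$ distinct
   shadowsamples drawn uniformly without replacement from the pool and
   $w \sim \mathrm{Dirichlet}(1, \dots, 1)$, i.e. uniform over the
   probability simplex. Averaging $N_{aff}$ perturbed cells concentrates
   the synthetic sample near the local minority mean, which is exactly the
   estimate one wants more of.

With all $\sigma = 0$ every synthetic cell lies in the convex hull of its
source neighborhood — the test suite checks this against an exact convex
feasibility oracle — so the noise scale alone controls how far synthetic
cells may leave the observed manifold.

## Rebalancing rule

With $N_{gen}$ set to `"auto"` (the default), each minority cell
contributes $\lfloor (n_{maj} - n_{min})/n_{min} \rfloor$ synthetic cells
and the first $(n_{maj} - n_{min}) \bmod n_{min}$ minority cells one more,
so after oversampling the two classes are *exactly* equal. The decision
threshold of 0.5 is then the neutral operating point.

# Tunable parameters

| parameter | default | meaning and rationale |
|---|---|---|
| `kNeighbors` | 30 | minority cells per oversampling neighborhood. For very small minorities a small value is appropriate (a 17-cell minority supports $k = 3$); `evaluateCV()`/`fitAnnotator()` shrink $k$ with a warning when a training fold has too few minority cells. |
| `sigma` ($L_\sigma$) | 0.005 × per-feature minority sd, floored at $10^{-6}$ | shadowsample noise. Small relative noise preserves the manifold; the scale adapts to each feature. Settable to a scalar or per-feature vector. |
| `nAff` ($N_{aff}$) | 50 if $n_{min} < 50$, else min(#features, 100) | shadowsamples per convex combination. More terms average closer to the local mean. |
| `nShadow` | $\lceil N_{aff}/(k+1) \rceil + 1$ | copies per neighborhood cell; the default guarantees the pool size $n_{shadow}(k+1) \ge N_{aff}$. |
| `nGen` ($N_{gen}$) | auto | synthetic cells per minority point; auto balances classes exactly. |
| `embedding`, `tsneMinPoints` | tsne, 50 | neighborhood space policy; t-SNE perplexity is min(30, (n−1)/3), seeded. |
| `knnK` | 30 | classifier neighbors, large enough that the vote rests on a statistically meaningful sample once classes are balanced. |
| `nFolds`, `nRepeats` | 5, 5 | stratified CV; use 3 folds when the minority is so small that 5 folds cannot each hold a minority cell (e.g. 17 cells). |
| threshold | 0.5 | decision threshold on the rare-class probability; user-adjustable to trade recall against precision. |

Classifier defaults are pinned so "default settings" are reproducible: the
logistic model is ridge-penalized (glmnet, $\alpha = 0$,
$\lambda = 1/n$ — the classical regularization strength $C = 1$ —
intercept fitted, iteration cap 1000); knn probability is the minority vote
fraction with distance ties broken by smaller training-row index.

# Pipeline hygiene

Cross-validation shuffles the data per repeat (repeat $r$ is seeded
`seed + r`) and deals each class round-robin over the folds, so per-fold
minority counts differ by at most one — every fold keeps approximately the
global imbalance ratio. Oversampling is applied **after** the split and
only to the training folds; synthetic rows are appended after the original
rows and carry a `"synthetic"` provenance flag, and test folds index
original rows only, so no synthetic cell is ever scored. Model selection
among candidate configurations ranks by mean F1 with ties broken by recall
then precision: when two models balance precision and recall equally well,
the more sensitive one is preferred, because missing rare cells is the
failure mode that motivates the method.

# The unsupervised baseline

`giniDbscan()` reproduces the discovery-style alternative the supervised
pipeline is compared against: compute the Gini index
$G = \sum_{i,j} |x_i - x_j| / (2 n^2 \bar x)$ of each candidate marker
across cells, min–max normalize, keep the 15 most unequal markers, and run
DBSCAN (eps 0.5, minimum cluster size 5, the point itself counting) on the
cells in that subspace. DBSCAN leaves two ambiguities that the textbook
algorithm resolves by scan order; here they are pinned so results are
reproducible: clusters are numbered by the row order of their first core
point, and a border point reachable from several clusters joins the
cluster of its smallest-row-index core neighbor. Clustering operates on
the same log-normalized scale as the supervised arm. A rare population
that is dense and well separated in marker space emerges as a small
cluster; a diffuse one falls below core density and is labeled noise —
the failure mode that motivates supervised annotation, and the behavior
the acceptance suite reproduces in kind.

# The synthetic data generator

`simulateCounts()` draws gene baseline means from a lognormal
(`meanlog = 0`, `sdlog = 1`), per-cell library scaling factors from a
lognormal (`sdlog = 0.2`), and counts from a negative binomial with size
(dispersion) parameter 2 — the minimal generative structure that matches
the overdispersion of real scRNA-seq counts. A rare cluster of
$\mathrm{round}(n_{cells}/(1 + IR))$ cells has the means of its
`nMarkers` marker genes multiplied by a fold change. Three presets encode
the regimes the pipeline is designed around:

* **easy** — fold change 8, size 2: a well-separated ultra-rare cluster
  (the cardiac-glial-like regime where even a baseline classifier does
  well);
* **hard** — fold change 2, size 1 (variance doubled relative to easy):
  a transient, overlapping population (the proliferative-cardiomyocyte-like
  regime where the baseline recall collapses and oversampling recovers
  it);
* **transfer** — identical gene-level parameters, drawn under a new
  cell-level seed. The generator separates a *biology seed* (gene means,
  marker identities) from a *cell seed*, so `transferConfig()` produces an
  unseen dataset of the same biology — the situation a transferred
  annotator faces.

Default problem sizes in the test and acceptance runs are 5 000 cells ×
200 genes at imbalance ratio 100 with 20 markers — large enough that CV
folds hold a meaningful number of rare cells, small enough that full
repeated CV over many generator seeds runs in minutes on one CPU.

The generator deliberately does **not** emulate batch effects, zero
inflation beyond the negative binomial, doublets, or trajectory structure.
Passing tests therefore demonstrate correctness of the algorithmic
machinery and the direction of the oversampling effect under realistic
imbalance and overdispersion; they do not certify performance numbers on
any real dataset, where annotation quality, batch structure and
normalization choices dominate.

# Numerical choices and degenerate inputs

* **Normalization** is `log(1 + count / total * 10^4)` with the natural
  logarithm; zero counts map to exactly zero and sparsity is preserved.
  Raw counts are also accepted throughout (`normalized = FALSE`); models
  record which scale they were trained on and refuse mismatched input.
  LogNormalized input is the default recommendation.
* **Welch t** (unequal variances) is used for the t-test ranking: with
  group sizes as asymmetric as 17 vs 8 618, pooling variances would let
  the majority dominate. Genes constant within both groups score 0 when
  the means agree and rank top when they differ (perfect separators).
* **ROC scores** are folded, $\max(\mathrm{AUC}, 1 - \mathrm{AUC})$, so
  down-regulated markers rank as high as up-regulated ones; AUC is
  computed by the rank-sum identity with midrank tie handling.
* **One-gene logistic scores** use a small ridge-IRLS on standardized
  expression (penalty matched to the classifier's $\lambda = 1/n$), so
  perfectly separating genes yield large finite coefficients instead of
  diverging.
* **Gini normalization** is min–max; a constant vector maps to all zeros
  (including the single-element case). All-zero expression has Gini 0 by
  convention.
* **Ties** are broken deterministically everywhere: neighbor ties by
  smaller row index, ranking ties by gene id, DBSCAN as described above.
* **Determinism**: every stochastic step (simulation, embedding,
  shadowsampling, combination, fold shuffling) runs under a seed derived
  from the relevant config, and seeded runs are bit-reproducible; the RNG
  state of the calling session is saved and restored.
* **Degenerate inputs** error early with specific messages: single-class
  labels, $k \ge n_{min}$, cells with zero total counts, an absent
  positive label name (preventing silent all-negative training), all
  requested genes missing. Missing genes at prediction time follow a
  configurable policy (default: zero-fill with a warning), because gene
  annotation drift between datasets is the norm, not the exception, in
  transfer use.

# Known limitations

* Binary annotation only: one rare type per model. Annotating several
  rare types means training one model per type, which also keeps each
  model's oversampling calibrated to its own imbalance.
* Oversampling trades precision for recall by design; on well-separated
  populations the baseline may have equal or better F1, and the
  oversampled model's advantage appears in recall and in transfer.
* knn prediction stores the full (oversampled) training matrix; for very
  large balanced training sets the logistic model is the economical
  choice.
* The t-SNE neighborhood embedding is used only above 50 minority cells;
  below that, raw-space neighborhoods are a deliberate approximation.
* No AUC reporting: with hundreds-to-one imbalance, ROC curves are
  dominated by the majority class; precision, recall and F1 are the
  metrics of record.
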