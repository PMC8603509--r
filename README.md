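# scLoras

Synthetic oversampling of rare cell types in single-cell and single-nuclei
RNA-seq data.

## The problem

Rare cell populations — glial cells in heart tissue, proliferative
cardiomyocytes, small interneuron subtypes — often make up fewer than 1 in
100 to 1 in 500 cells. Once such a population has been expert-annotated in
one dataset, the natural next step is to find the same cells automatically
in new datasets. Treated as supervised classification this is a severely
imbalanced problem: with an imbalance ratio of several hundred, a classifier
that never predicts the rare class still looks excellent on accuracy, and
unsupervised rare-cell discovery (Gini-index marker selection plus density
clustering) can perceive a genuine rare cluster as noise.

scLoras addresses this with **LoRAS** (Localized Random Affine
Shadowsampling), a synthetic oversampling scheme for the minority class.
For each rare cell *p*:

1. take the *k* nearest minority cells of *p* (in a 2-D t-SNE embedding of
   the minority class when it is large enough, otherwise in raw feature
   space);
2. perturb each cell of this neighborhood with per-feature Gaussian noise
   (standard deviations *L<sub>σ</sub>*), producing a pool of
   *shadowsamples*;
3. draw a synthetic cell as a random convex combination of
   *N<sub>aff</sub>* shadowsamples, with flat-Dirichlet weights *w*
   (*w<sub>i</sub>* ≥ 0, Σ*w<sub>i</sub>* = 1) — a random weighted average
   of perturbed rare cells that stays on the local minority manifold.

Generating *N<sub>gen</sub>* synthetic cells per minority point (chosen
automatically so that the classes balance exactly) turns the imbalanced
problem into a balanced one. Around this core the package provides marker
gene ranking (Welch t, ROC AUC, ridge-logistic scores), stratified repeated
cross-validation in which oversampling is applied to the training folds
only, knn (k = 30) and L2-logistic classifiers scored by precision, recall
and F1, transfer prediction onto unseen datasets, a Gini/DBSCAN unsupervised
baseline, and a negative-binomial simulator of imbalanced single-cell data
so every stage is testable offline.

## Worked example

The `"hard"` simulation preset emulates a transient cell state: a rare
cluster (imbalance ratio 100) whose markers are only 2-fold elevated over an
overdispersed negative-binomial background, so it overlaps its neighbors.

```r
library(scLoras)

sim <- simulateCounts(simConfig("hard", seed = 1))
sim$matrix
#> CountMatrix: 5000 cells x 200 genes (dense, raw counts)
sim$labels
#> CellLabels: 5000 cells, 50 minority (rare), 4950 majority

norm  <- logNormalize(sim$matrix)                  # ln(1 + count/total * 1e4)
d     <- alignAndSubset(norm, sim$labels, geneIds(norm))
top20 <- topMarkers(rankMarkers(d, "ttest"), 20)   # feature pre-selection
d20   <- alignAndSubset(norm, sim$labels, top20)
round(imbalanceRatio(d20), 2)
#> [1] 99

baseline <- evaluateCV(d20, cvConfig(nFolds = 5, nRepeats = 5, seed = 1,
                                     oversample = FALSE))
scsyno   <- evaluateCV(d20, cvConfig(nFolds = 5, nRepeats = 5, seed = 1,
                                     oversample = TRUE))
baseline
#> CVReport [baseline]: 25 folds; precision 0.000+-0.000 recall 0.000+-0.000 f1 0.000+-0.000
scsyno
#> CVReport [scsyno]: 25 folds; precision 0.065+-0.010 recall 0.676+-0.120 f1 0.119+-0.018
```

The baseline knn never calls a single rare cell (recall 0.000): with 40
minority cells among ~4000 training rows, a 30-neighbor vote is always
dominated by the majority. After fold-wise LoRAS oversampling the same
classifier recovers two thirds of the held-out rare cells (recall 0.676) —
oversampling buys detection rate at a precision cost, which is the right
trade when the goal is not to miss rare cells.

Transfer to an unseen dataset of the same biology (here the `"easy"`
well-separated preset):

```r
cfgTrain <- simConfig("easy", seed = 1)
sim  <- simulateCounts(cfgTrain)
norm <- logNormalize(sim$matrix)
d20  <- alignAndSubset(norm, sim$labels,
                       topMarkers(rankMarkers(
                         alignAndSubset(norm, sim$labels, geneIds(norm)),
                         "ttest"), 20))
ann <- fitAnnotator(d20, cvConfig(oversample = TRUE, seed = 1))
ann
#> TrainedAnnotator: knn on 20 genes (log-normalized scale), threshold 0.50, LoRAS-oversampled

unseen <- simulateCounts(transferConfig(cfgTrain, seed = 101))
pred   <- predict(ann, logNormalize(unseen$matrix))
round(classificationMetrics(labelVector(unseen$labels), pred$label), 3)
#> precision    recall        f1
#>     0.877     1.000     0.935
```

Every rare cell of the unseen dataset is found (recall 1.000) at precision
0.877.

A command-line front end over the same functions ships in
`inst/scripts/scsyno.R` (`simulate | rank | crossval | train | predict |
discover`).

## Vignette

`vignettes/rare-cell-oversampling.Rmd` documents the model and its
assumptions, every tunable parameter with its default and rationale, what
the simulator does and does not emulate, and known limitations.
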