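---
title: "Labelling and predicting context-specific essential genes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Labelling and predicting context-specific essential genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crisprEssentials)
```

## The problem

Genome-wide CRISPR knockout screens assign every (gene, cell line) pair a
real-valued *gene-effect score*: the fitness change observed after knocking
the gene out, with more negative values meaning stronger growth inhibition.
A gene is *essential* in a context — a tissue, a disease, any user-defined
set of cell lines — when its knockout is deleterious across the cell lines
of that context. Essentiality is neither binary nor organism-wide: besides
the *common* essential genes (cEGs) required by virtually every cell, some
genes are essential only in specific contexts (csEGs), and the most
interesting ones are those context-specific genes that are *not* common
(ucsEGs), candidate context-selective targets.

This package does two things:

1. **Labelling** (unsupervised): derive E/NE labels per context directly
   from a score matrix, with a refinement that splits NE into
   almost-essential (aE) and strongly-not-essential (sNE).
2. **Prediction** (supervised): learn those labels from gene attributes —
   multi-omics features and network embeddings of a protein–protein
   interaction (PPI) graph — with an ensemble built for the strong class
   imbalance of the problem (roughly 7% essential).

## The labelling model

For a context \(C\) with cell lines \(c \in C\):

1. **Select** the columns of the score matrix belonging to \(C\).
2. **Binarise** each column at a threshold \(t_c\) chosen by Otsu's
   criterion — the cut maximising the between-class variance
   \(w_0 w_1 (\mu_0 - \mu_1)^2\) of the column's score distribution. A
   score \(s_{g,c} < t_c\) yields the partial label E, \(s_{g,c} \ge t_c\)
   yields NE. The per-cell-line score distribution is strongly bimodal (a
   large mode near 0, a depleted mode of essential genes well below it),
   which is exactly the regime Otsu's criterion was designed for.
3. **Aggregate** each gene's partial labels by their mode; an even E/NE
   split resolves to NE, the conservative choice.

Common essential genes use a *two-level* mode: the context-level labelling
is run for every context, and each gene's final label is the mode of its
per-context labels (ties again to NE). This gives every context one vote
regardless of how many cell lines it contributed, so a heavily sampled
tissue cannot dominate. The uncommonly context-specific set is then the
plain set difference ucsEG(\(C\)) = csEG(\(C\)) \ cEG.

The three-class refinement keeps E fixed, restricts every column to the
genes whose final context label is NE, reruns the Otsu binarisation on the
restricted distribution (partial labels aE below the second threshold, sNE
at or above it), and aggregates by mode with ties to sNE. By construction
E, aE and sNE partition the labelled genes.

### Numerical choices

* **Histogram resolution.** Otsu's criterion needs a histogram; we use 256
  bins spanning `[min, max]` of the finite scores, the canonical choice in
  image processing, and accumulate exact per-bin value sums so that the
  between-class variance at every candidate cut is computed exactly rather
  than from bin midpoints. The returned threshold is the upper edge of the
  winning bin, so the resolution error is bounded by `range/256`; the test
  suite checks the resulting partition against an exhaustive scan of all
  midpoints between consecutive sorted values.
* **Boundary.** A score exactly at the threshold is NE: the label-defining
  comparison is strict (`score < t`), assigning the boundary to the
  majority class.
* **Missing scores** are excluded from both threshold estimation and the
  mode; a gene with no usable score in a context is omitted from that
  context's assignment (and reported). No imputation happens at the
  labelling stage.
* **Constant columns** carry no evidence of essentiality; they label every
  gene NE and log a warning rather than fail.
* **Pre-filters.** Contexts with fewer than 10 cell lines are dropped (a
  mode over a handful of columns is not meaningful), then genes missing in
  strictly more than 95% of the remaining cell lines are dropped; a gene
  at exactly 95% is kept.
* **Second-pass restriction.** The aE/sNE pass restricts genes by their
  *final context-level* NE label, applied uniformly to every cell line —
  not by per-cell-line partial labels. Both readings are defensible; the
  uniform restriction keeps every column's restricted gene set identical,
  which makes the pass reproducible column by column and keeps the
  three-class output an exact partition.

## PPI node embeddings

Topological features come from biased second-order random walks with a
skip-gram objective (the node2vec construction). From every non-isolated
node we start 10 walks of length 80; the transition weight from previous
node \(t\) through the current node to neighbour \(x\) with edge weight
\(w\) is \(w/p\) if \(x = t\), \(w\) if \(x\) neighbours \(t\), and
\(w/q\) otherwise. Edge confidences (e.g. combined scores already filtered
at 0.5) are used as walk weights. The walk corpus trains skip-gram with
negative sampling (window 10, 5 negatives, 5 epochs, unigram^0.75 negative
distribution, linearly decaying learning rate), implemented in compiled
code inside the package and driven entirely by R's RNG, so a single seed
makes walks and training bit-reproducible. Defaults: 128 dimensions,
\(p = q = 1\) — the original node2vec baseline, since nothing in the
problem argues for a BFS- or DFS-skewed neighbourhood.

## The splitting voting ensemble

With ~7% positives, a single classifier trained on the full data buys
specificity at the price of sensitivity. The ensemble instead partitions
the *majority-class* training rows into
\(n = \max(1, \lfloor N_{maj}/N_{min} \rfloor)\) slices (seeded shuffle,
round-robin deal, sizes within one of each other), trains one base learner
per slice together with *all* minority rows — so each member sees a
roughly balanced set while the ensemble still uses every sample once, with
no subsampling, oversampling or synthetic data — and predicts by *soft
voting*: the arithmetic mean of the members' positive-class probabilities.
A hard label is positive when the mean probability reaches the 0.5
threshold (boundary to the positive class).

The base learner is a pluggable contract (`fit(x, y)` /
`predict(model, x)`); the default is a gradient-boosted decision-tree
classifier (xgboost, single-threaded for determinism, 100 rounds, depth 4,
learning rate 0.3 — shallow trees are appropriate for members that see a
few hundred rows), and a random-forest learner is provided as an
alternative. The slice partition scheme (shuffle + round-robin) is our
choice; it is deterministic given the seed and guarantees the ±1 size
balance the member-balance argument relies on.

## Evaluation harness

Validation uses stratified 5-fold cross-validation repeated over 10 rounds
with a different partition per round (round seed = run seed + round
index). Folds are dealt through one continuing round-robin cursor across
classes, so both total fold sizes and per-fold positive counts differ by
at most one. Within each fold, preprocessing — median imputation,
constant-column removal, z-scoring of the Bio/CCcfs groups (the embedding
columns are left on their native scale) — is fitted on the training folds
only and applied to the held-out fold, so no statistic leaks from test
rows. Whether the original normalisation was global or fold-wise is not
something we could determine; fold-wise is the leak-free reading and may
shift metrics slightly relative to a global fit.

Each round predicts every gene exactly once; the round's pooled confusion
gives Sensitivity, Specificity, their mean (Balanced Accuracy, the metric
of record under imbalance), MCC, and a rank-statistic ROC-AUC with
midrank tie handling. The report carries per-round confusions (so metrics
can be recomputed independently), per-gene probability means and standard
deviations over rounds, and subset recall (e.g. on a ucsEG list) for a
chosen round — by default round 1, with the mean over rounds alongside.
Genes that carry a label but no feature row cannot be predicted; they are
excluded from matrices and denominators and reported.

## What the synthetic generators emulate

The score generator plants, per context, an essential set (7% prevalence
by default) drawing scores from \(\mathcal N(-1.5, 0.3^2)\) against a
not-essential mode \(\mathcal N(0, 0.2^2)\), 5% missing entries placed
uniformly, three contexts of 30/20/10 cell lines, and a shared core plus
context-private essential genes (20% of each context's set) so the
common/ucs subtraction has an exact planted answer. The modes sit several
standard deviations apart — any reasonable threshold separates them — so
label-recovery assertions test the machinery, not threshold luck; an
overlapping-modes configuration can be dialled in for stress tests. An
optional intermediate layer between the modes exercises the three-class
pass. The graph generator produces planted-partition communities with
confidence weights in \([0.5, 1]\); the feature generator produces
class-conditional Gaussians with a configurable shift on half the columns,
plus injectable constant columns and a zero-shift null mode.

What the generators deliberately do **not** emulate: the covariance
structure of real screens (off-target and copy-number artefacts, correlated
cell lines), realistic attribute distributions (heavy-tailed counts,
block-correlated annotation features), or scale-free PPI topology. Passing
tests therefore demonstrate correctness of the algorithms under controlled
conditions, not performance on real DepMap-scale data; the headline
numbers reported on real screens in the literature depend on those data
and on curated multi-omics tables, and are out of reach of a
self-contained test bench.

## Problem sizes used by the test bench

The shipped checks run the labelling recovery at 3,000 genes × 60 cell
lines, the ensemble benefit and null checks at 2,000 and 1,000 genes × 20
features over 10×5-fold CV, the embedding separation on a 2×50-node
planted-partition graph across 5 seeds, and the pipeline determinism check
at 300 genes with 16-dimensional embeddings. These sizes give stable
statistics while keeping a full run in the low minutes; all of them are
parameters, and the same code paths run unchanged at screen scale.

## Known limitations

* The labelling inherits Otsu's assumptions: a clearly bimodal per-column
  distribution. Columns with weak depletion signal produce unstable
  thresholds; the mode over cell lines absorbs some of this, and the
  per-cell-line threshold sidecar exists precisely so users can audit it.
* Gene identifiers are joined by plain symbol across scores, features and
  graphs (a trailing `"(ENTREZ)"` token is stripped on read); no
  identifier-mapping service is consulted, so synonyms are the user's
  responsibility.
* The aE/sNE boundary is a second Otsu cut inside a distribution that is
  usually *not* strongly bimodal; treat aE membership as a ranking signal
  rather than a sharp class.
* With `n = 1` (majority barely exceeds minority) the ensemble degenerates
  to its base learner, by design.
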