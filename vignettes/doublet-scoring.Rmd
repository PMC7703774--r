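---
title: "Doublet scoring: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Doublet scoring: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

Droplet-based single-cell RNA-seq occasionally captures two cells under one
barcode. These *doublets* masquerade as single cells — often as spurious
intermediate "cell types" — and can derail any downstream analysis that
reasons about cellular identity. `doubletscore` annotates each barcode of a
genes × cells count matrix with scores that rank it from most to least
doublet-like. It does not decide how many doublets there are; that number
is best taken from the experimental design (e.g. loading-density tables),
after which the top-ranked barcodes can be flagged.

This vignette documents the two scoring models, their tunable parameters,
the evaluation toolkit, the synthetic-data generator, and the numerical and
design decisions that are not obvious from the function reference.

## Co-expression scoring (cxds)

The model rests on a simplified notion of marker genes: genes expressed in
one cell type and silent in others. A barcode that co-expresses markers of
two different types is suspicious. Rather than requiring curated markers,
all gene pairs are scored from the data itself.

Let $X \in \mathbb{N}^{m \times n}$ be the count matrix and $B$ its
binarized version, $B_{ij} = 1$ iff gene $i$ has more than `bin_thresh`
counts in cell $j$. With $p_i$ the fraction of cells expressing gene $i$
and genes assumed independent, the number of cells expressing *exactly one*
of genes $i$ and $j$ is

$$ (B\bar{B}^\top + \bar{B}B^\top)_{ij} \sim
   \mathrm{Bin}\!\left(n,\; p_i(1-p_j) + p_j(1-p_i)\right), $$

where $\bar B = 1 - B$. The pair score $S_{ij}$ is the negative natural log
of the inclusive upper-tail p-value of that count. Marker pairs of two
different cell types co-express *less* often than their margins predict
(the exactly-one count falls short of the null), so they score high; pairs
that co-express freely score near zero. The per-cell score sums the scores
of all pairs the cell co-expresses:

$$ \mathrm{cxds}(i) = \sum_k \sum_j B_{ki}\,B_{ji}\,S_{kj}
                    = \mathrm{diag}(B^\top S B)_i. $$

Because the score is a plain sum, it decomposes: the importance of pair
$(k, j)$ across the dataset is
$\mathrm{imp}(k,j) = \sum_i \mathrm{cxds}(i) B_{ki} B_{ji} S_{kj}
= ((B D B^\top) \circ S)_{kj}$ with $D$ the diagonal matrix of cell
scores. `top_pairs()` ranks pairs by it; restricting $D$ to a cell subset
attributes scores to a cluster or a single cell. Summed over all ordered
pairs the importance equals $\sum_i \mathrm{cxds}(i)^2$, which the test
suite uses as a conservation oracle.

Parameters:

* `bin_thresh` (default 0 counts): presence means *strictly more than*
  this many counts. Zero treats any detected UMI as presence, appropriate
  for sparse UMI data; deeper or noisier protocols may warrant 1–2.
* `ntop` (default 500 genes): pairs are only scored among the `ntop` genes
  with the largest binomial variance $n p (1-p)$ of their detection
  frequency, computed after binarization. Genes detected nowhere or
  everywhere carry no pairing information and are never selected.

Conventions chosen where the mathematics leaves slack:

* The upper tail is **inclusive**, $P(K \ge k)$, so $k = 0$ — and hence
  every diagonal entry of $S$ — scores exactly 0. Self-pairs can therefore
  be kept in the matrix algebra; they contribute nothing.
* Each unordered pair enters the double sum twice. The factor 2 is kept
  (the matrix identity is then exact); only ranks matter downstream.
* All logs are natural. Scores are compared within a dataset only.
* Pair log-p-values below $-745$ (the double underflow boundary) are
  capped so that downstream sums stay finite; capped pairs are reported
  via a `message()`.

## Classification scoring (bcds)

Instead of modeling co-expression, bcds manufactures what it is looking
for. `n_art` artificial doublets (default: one per real cell, giving
balanced classes) are built by summing the counts of two distinct,
uniformly drawn cells — the in-silico analogue of two cells sharing a
droplet. Gradient boosted trees (xgboost, library defaults, binary
logistic objective) then learn to separate artificial doublets from real
barcodes on gene-wise centered $\ln(1+\mathrm{count})$ features over the
`ntop` (default 500) most log-variable genes, selected on the original
cells before any simulation. A real barcode's doublet score is the trained
model's probability that it belongs to the artificial class. Real doublets
resemble the artificial ones and are hard to separate, so they score high.

The number of boosting rounds is the one knob that matters, and two
heuristics are provided:

* `rounds_mode = "cv_one_se"` (default): 5-fold cross-validation on the
  augmented data tracks the per-round mean misclassification error and its
  standard error across folds (sd/$\sqrt{K}$). Training stops once the
  mean error has failed to decrease relative to the previous round for two
  consecutive rounds (capped at `max_rounds`, default 500), and the
  one-standard-error rule picks the smallest round whose error is within
  one SE of the minimum. A slack of $10^{-10}$ keeps rounds that sit
  exactly on the threshold from being excluded by floating-point round-off.
* `rounds_mode = "fixed7"`: at most seven rounds, with the same
  two-consecutive-rounds stopping check applied to the training error on
  the full augmented set. Roughly three times faster; the scores correlate
  strongly with the CV variant (Pearson ≈ 0.9 on simulated data) though
  the global *rank* correlation is diluted by the near-zero singlet scores,
  whose relative order is essentially arbitrary under both variants.

Design points decided here:

* "Mean-normalization of log counts" is implemented as **gene-wise**
  centering over the augmented set (original cells and artificial doublets
  together). Per-cell centering is a defensible alternative; the choice is
  isolated in `normalize_logcounts()` so swapping it is a one-line change.
* Doublet parents are distinct (no cell summed with itself) but pairs are
  drawn independently, so one cell may parent several doublets.
* Original cells are scored in-sample, by the model trained on data that
  includes them. That is deliberate: the goal is an annotation of this
  dataset, not generalization to new data.
* Early stopping compares round $r$ against round $r-1$ ("did not
  decrease" means $\ge$), with two consecutive failures required. The CV
  loop trains each fold one round at a time (model continuation), so the
  rule applies to the *mean* CV error exactly as stated rather than to
  each fold separately.
* A `seed` is mandatory: parent sampling and fold assignment are random,
  and with a fixed seed (and xgboost on one thread) the whole pipeline is
  bit-reproducible — score CSVs are byte-identical across runs.

## Hybrid score

Both scores are min-max normalized, $(v - \min v)/(\max v - \min v)$, and
added, giving a score in $[0, 2]$ that is invariant to positive affine
transforms of either input. The normalization denominator uses the full
range rather than the bare maximum — with a nonzero minimum the latter
would not reach 1, defeating the purpose of putting both methods on a
common scale. A constant score vector carries no information and maps to
all zeros, so the hybrid then degenerates gracefully to the other method.

## Evaluation toolkit

`evaluate_scores()` reports, per method: AUROC (trapezoidal, equal to the
tie-corrected Mann–Whitney statistic; computed via pROC), corrected
partial AUC at 90/95/97.5% specificity, and the Davis–Goadrich AUPRC.

* The partial AUC integrates the ROC over specificity $[s, 1]$ with linear
  interpolation at the boundary and is standardized as
  $0.5\,(1 + (A - A_{\min})/(A_{\max} - A_{\min}))$ with
  $A_{\max} = 1-s$, $A_{\min} = (1-s)^2/2$, so 1 is perfect and 0.5 is
  chance. The standardization is applied to pROC's raw partial area by
  this package rather than by pROC, because it must remain defined (below
  0.5) for partial curves under the chance line.
* The AUPRC uses the Davis–Goadrich nonlinear interpolant between
  achievable PR points — between points $a$ and $b$, precision at
  $\mathrm{TP} = x$ is $x/(x + \mathrm{FP}_a + s(x - \mathrm{TP}_a))$ with
  $s$ the local FP/TP slope — integrated segment-by-segment in closed
  form over recall $(0, 1]$. Linear interpolation in PR space is biased
  upward; the DG area always lies between the step-wise and linear areas,
  which the tests assert on random instances.
* `call_top_k()` mirrors the standard comparison protocol: call exactly as
  many doublets as are annotated, then partition cells into TP/FP/FN/TN
  (`confusion_classes()`).
* `stratified_eval()` bins cells into library-size quantiles (ties on a
  boundary go to the lower bin) and reports per-bin AUROC/AUPRC; bins
  containing a single class yield `NA`, never an error, since low-depth
  strata routinely hold no annotated doublets.
* `enrichment_heterotypic()` tabulates recovered vs missed doublets
  against heterotypic vs homotypic and reports the odds ratio (0.5 Haldane
  correction if any cell is empty) with Fisher's exact p-value.
* `baseline_scores()` provides the two no-model baselines every doublet
  caller should beat on real data: total counts and detected genes.

Ranks throughout the package run from 1 (most doublet-like) down, with
ties broken by input order so repeated runs produce identical tables.

## The synthetic-data generator

`simulate_doublets()` produces the reference conditions the test suite and
the acceptance script run under: `n_types` cell types with mutually
exclusive marker blocks (`markers_per_type` genes at negative-binomial
mean `mu_marker` in their own type, `mu_background` elsewhere, shared
dispersion), plus `round(doublet_rate * n)` doublets formed exactly as
real doublets arise — two realized singlets drawn from the pool, counts
summed, replacing a singlet so the cell total is unchanged. Defaults
(3 × 500 cells, 1000 genes, 50 markers/type, means 5 vs 0.1, dispersion 2,
10% doublets) sketch a modest 10x-style experiment: ~90 detected genes
per singlet, ~77% matrix sparsity, a realistic doublet rate.

What the generator deliberately does **not** emulate, and what that means
for interpreting green tests:

* **No library-size variation.** Every singlet has the same expected
  depth, so a doublet's ~2× depth makes total counts a *perfect*
  classifier here (AUROC 1.0) — unlike real data, where depth varies over
  orders of magnitude and the baselines are mediocre. Passing recovery
  tests therefore demonstrates that cxds/bcds/hybrid find the doublet
  signal (they reach AUROC ≥ 0.99 without using depth directly), not that
  they beat depth-based baselines on this simulation; nothing can beat a
  perfect classifier.
* No ambient RNA, batch effects, or transitional states — real
  false-positive sources that the simulation cannot surface.
* Homotypic doublets are present (same-type parents, ~1/3 of doublets
  under three equal types) and behave as in real data: cxds sees them only
  through their elevated gene detection, so its heterotypic enrichment
  odds ratio is large (≈ 60 under the defaults), echoing the known
  heterotypic bias of co-expression methods.

## Problem sizes

The test suite and `scripts/acceptance.R` were sized to run comfortably on
a single CPU: the reference simulation is 1500 cells × 1000 genes (about
15 s for all five scorers, dominated by the bcds cross-validation); the
binomial-tail oracle sweeps all $0 \le k \le n \le 200$ against 101 null
probabilities; matrix-identity oracles use 100 random instances up to
50 genes × 200 cells; and a 12 000-cell × 500-gene matrix exercises the
sparse path end to end. The determinism check runs the full
simulate–score–evaluate pipeline twice at 450 cells and compares output
bytes.

## Known limitations

* The number of doublets is not estimated; scores are rankings.
* cxds is blind to homotypic doublets beyond their depth signature — a
  limitation shared by all co-expression reasoning.
* Scoring assumes doublets are rare and that the single-cell instances of
  the mixed types are well represented.
* bcds inherits xgboost's hyperparameter surface untouched; tuning could
  help but risks overfitting to the handful of annotated datasets that
  exist, so the defaults are kept.
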