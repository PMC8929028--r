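---
title: "Measuring HiChIP/PLAC-Seq reproducibility: model, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring HiChIP/PLAC-Seq reproducibility}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hprep)
```

## The problem

HiChIP and PLAC-Seq capture long-range chromatin contacts that are
anchored at the binding sites of a targeted protein (typically a histone
mark such as H3K4me3 or H3K27ac). Two features distinguish the resulting
data from Hi-C. First, the immunoprecipitation step introduces a
sample-specific enrichment bias: the same underlying contact map read
through two ChIP libraries of different efficiency yields systematically
different counts. Second, the data are not a full symmetric bin-by-bin
matrix: only bin pairs with at least one end in a peak ("anchor") bin are
informative. A reproducibility measure for these assays has to normalize
the enrichment away and respect the anchor-centric geometry, which is
what this package does.

## Normalization model

Observed long-range (> 1 Kb separation) contact counts are necessarily
non-zero — a pair absent from a contact file was simply not observed — so
the counts are modeled with a zero-truncated Poisson (ZTP). For bin pair
$(i, j)$:

$$\log \mu_{ij} = \beta_0 + \beta_1 \mathrm{FL}_{ij} + \beta_2 \mathrm{GC}_{ij}
  + \beta_3 \mathrm{MS}_{ij} + \beta_4 \mathrm{IP}_{ij},
  \qquad Y_{ij} \sim \mathrm{Poisson}(\mu_{ij}) \mid Y_{ij} > 0 .$$

Each covariate is $\log(x_i x_j)$ of a per-bin feature: effective
fragment length, GC content, mappability, and the short-range ($\le$ 1 Kb)
read count, the last serving as a per-bin proxy for ChIP efficiency.
Separate models are fitted for AND pairs (both ends anchors, doubly
enriched) and XOR pairs (one end an anchor) on each chromosome, because
the two classes sit at very different enrichment levels. Pairs with no
anchor end (NOT) carry no protein-centric signal and are excluded.

The normalized contact value is $\log_2(1 + \text{observed}/\text{fitted})$:
1 when a pair is observed exactly at its model expectation, above 1 when
enriched.

**What "fitted" means.** For a model of strictly positive counts the
natural fitted value is the truncated mean
$E[Y \mid Y > 0] = \mu / (1 - e^{-\mu})$, and that is the default here
(`predict_fitted(..., type = "truncated")`). The raw mean $\mu$ is also
exposed (`type = "mean"`); the two coincide for $\mu \gtrsim 10$ and the
choice only matters for sparse, low-count cells.

**Fitting.** The ZTP score is $X^\top(y - E[Y\mid Y>0])$ and the observed
information equals the expected information, so Newton–Raphson and Fisher
scoring coincide. The fit starts from the ordinary Poisson log-linear
coefficients, takes damped Newton steps (step-halving when a step would
reduce the likelihood), and declares convergence when the gradient
$\infty$-norm falls below $\max(10^{-8},\ 10^{-12} \sum y)$. The second
term matters only at very high depth: the gradient is a sum of order
$\sum y$, so its attainable floating-point floor grows with the total
count, and a fixed $10^{-8}$ would spuriously flag non-convergence on
deep libraries while being exactly the operative tolerance at the
problem sizes where exact optimizer agreement is tested. Fits need at
least 50 pairs — below that the MLE is too unstable to be useful and the
chromosome/class cell is skipped with a warning — and rank-deficient
designs are refused with the collinear covariates named, rather than
silently dropped.

## The anchor-by-offset matrix and smoothing

Normalized AND and XOR values are arranged in an $N \times m$ matrix:
rows are the union of all samples' anchor bins ($N$), columns the signed
offsets $j \in \{-m/2, \dots, -1, 1, \dots, m/2\}$ in bin widths, with
$m = 2 \cdot \text{binning distance} / \text{resolution}$ (400 columns at
5 Kb, 200 at 10 Kb for the default 1 Mb distance — contacts past 1 Mb
are sparse and highly variable, hence the cutoff). Cells never written
are 0, which downstream is treated as "no observed contact".

Two placement choices were genuinely open:

* **AND pairs populate both anchor rows** (at opposite-signed offsets).
  The matrix is anchor-centric and both ends of an AND pair are anchors;
  writing only one row would make the result depend on an arbitrary
  ordering of the two ends.
* **There is no offset-0 column**, and the smoothing window runs over
  column indices, so offsets $-1$ and $+1$ are adjacent. The offset set
  excludes 0 by construction (a bin does not contact itself at this
  resolution), and treating the gap as a missing column would let the
  window silently shrink at the center.

Smoothing replaces each cell by the mean of the $2d + 1$ cells within
$d$ columns in the same row, with cells beyond the matrix edge
contributing 0 and the divisor fixed at $2d + 1$. This zero-padding
convention follows the averaging formula as written; its side effect —
values within $d$ columns of the $\pm$ 1 Mb edge shrink toward 0 — is
shared by both samples being compared and does not favor either.

## The score

For stratum $k$, concatenate columns $-k$ and $+k$ of each sample's
matrix (length $2N$), drop positions that are 0 in both samples, and
compute the Pearson correlation $r_k$ of the remainder using population
($1/N_k$) moments. Strata are combined as
$\sum_k r_k w_k$ with $w_k \propto N_k\, \sigma(a'_k)\, \sigma(b'_k)$,
normalized so $\sum_k w_k = 1$: large, variable strata — where a
correlation is actually estimable — dominate. Population rather than
sample moments follow the defining formulas; the distinction cancels in
$r_k$ but not in $w_k$ (the ratio $N_k/(N_k - 1)$ would re-weight small
strata slightly).

A stratum with fewer than two retained positions, or zero variance in
either vector, has no defined correlation; it receives weight 0 and is
excluded from the weight denominator, preserving $\sum w_k = 1$. If
every stratum is undefined the pair's score is reported as missing, not
forced to a number. Genome-wide scores are the unweighted arithmetic
mean over chromosomes (depth differences between chromosomes are real,
but the per-chromosome scores are already normalized quantities; a
read-weighted mean would let one deep chromosome dominate).

## Smoothing-parameter tuning

For candidate $d = 0, 1, 2, \dots$: draw ten independent subsamples of
25% of sample A's non-zero matrix cells (without replacement), zero the
rest, restrict B to the same positions, score each subsampled pair at
smoothing $d$, and average. Stop at the first $d$ for which the average
at $d + 1$ improves by less than one percent, and use that $d$ for every
pair in the study. Two readings were open:

* *Cells vs. reads.* The subsample is of non-zero **matrix cells**, not
  raw reads. The procedure operates on the populated contact matrix, and
  cell-level subsampling is what "sampling the non-zero contacts" means
  at that stage.
* *Relative vs. absolute 1%.* The increase is **relative**
  (mean$(d{+}1) < 1.01 \cdot$ mean$(d)$). Scores are unit-bounded, so a
  relative threshold adapts to where on $[-1, 1]$ the trajectory sits.
  For trajectories near 0 or negative the relative rule is conservative
  and stops early, which is the safe direction (less smoothing).

Tuning against a dissimilar pair (non-replicates) is recommended: a
self-comparison starts at score 1 and terminates immediately at $d = 0$.

## Resampling utilities

**Downsampling** to factor $f$ replaces a file's count vector $v$
(total $n$) by a draw from $\mathrm{Multinomial}(\lfloor nf \rfloor, v/n)$,
separately per (chromosome, class) file, then removes pairs drawn to 0.
The total after downsampling is exactly $\lfloor nf \rfloor$ for every
seed. **Pseudo-replicates** pool two same-condition samples over the
union of their bin pairs and split each pooled count $c$ into
$\mathrm{Binomial}(c, 1/2)$ and its complement — two artificial samples
that differ only by sampling noise, an upper reference for attainable
similarity. Pseudo-replicates re-enter the pipeline from the
normalization step like any other sample. Every stochastic operation
derives a stream from a stable hash of (master seed, sample, chromosome,
class), so adding a sample to a study never perturbs another sample's
draws.

## Silhouette evaluation

Pairwise scores are first min–max scaled to $[0, 1]$ using the
**off-diagonal** minimum and maximum — the silhouette needs ratio-scale
quantities, and including the self-similarity of 1 would anchor the
maximum and compress the informative range. For sample $i$ in cluster
$A$, $a(i)$ is its mean similarity to the rest of $A$, $b(i)$ the
largest mean similarity to any other cluster, and
$s(i) = (a(i) - b(i)) / \max(a(i), b(i))$; the package reports the mean
over samples. Because these are similarities (not distances), good
clustering drives $s$ toward $+1$. Samples in singleton clusters have no
within-cluster average and get $s(i) = 0$, the usual neutral convention.

## The synthetic-study generator

`simulate_study()` builds complete studies so that the whole pipeline is
testable without any external download. It emulates:

* per-bin features with realistic ranges (effective length 0.5–1 ×
  resolution, GC 0.3–0.7, mappability 0.7–1) and short-range counts
  enriched 5-fold at anchor bins, mimicking ChIP pull-down;
* condition-specific anchor sets with a controlled pairwise Jaccard
  overlap (default 0.54, the regime of promoter marks shared across
  tissues; 0.32 emulates more divergent marks), emitted as BED peaks in
  which runs of adjacent anchor bins become single boundary-spanning
  peaks, exercising the peak-binning rule;
* counts drawn Poisson — hence, conditional on presence in the file,
  zero-truncated — from
  $\log \mu = \beta^\top x + \text{loop signal} - \gamma \log(\text{distance}) + \varepsilon$,
  with a sparse condition-level field of elevated "loop" cells shared by
  replicates, power-law distance decay ($\gamma = 1$ by default), and
  replicate-specific log-normal noise (sd 0.2);
* a handful of background pairs away from anchors, so AND, XOR and NOT
  classes all occur.

Defaults are 2 chromosomes × 2,000 bins at 10 Kb with an expected
200,000 long-range contacts per sample — a desk-scale study that runs
the full pipeline in seconds. The generator does **not** model
restriction-fragment structure, ligation artifacts, trans contacts, copy
number, or mapping errors; passing tests on synthetic studies show that
the pipeline's statistics behave as designed under its own generative
assumptions, not that real libraries satisfy those assumptions.

The test suite runs its study-level checks at a reduced scale (one
chromosome of 800 bins, depth $5 \times 10^4$, 2–3 replicates per
condition), which preserves every qualitative behavior of the default
scale. Stochastic trend checks — e.g. that the silhouette degrades as
samples are downsampled from 100% to 20% — average the trajectory over
several independent study draws, because a single study's trajectory
carries Monte Carlo jitter of the same order as the effect at adjacent
factors.

## Known limitations

* The regression assumes the log-linear bias model is correct; gross
  overdispersion beyond what the covariates absorb will deflate fitted
  values' quality, and no negative-binomial alternative is provided.
* Scores compare samples on the **union** anchor set, so a sample pair's
  score reflects 1D peak-set disagreement as well as 3D contact
  disagreement — by design, but worth remembering when anchor sets are
  nearly disjoint.
* Zero cells are indistinguishable from unobserved cells; at very low
  depth the joint-zero removal discards most of each stratum and the
  score becomes noisy before it becomes undefined.
* The 1% tuning rule compares adjacent candidates only; a trajectory
  with a flat shoulder followed by late gains would stop at the
  shoulder.
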