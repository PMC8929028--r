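# hprep

Reproducibility metrics for HiChIP and PLAC-Seq chromatin-interaction data.

HiChIP and PLAC-Seq ("HP" assays) combine proximity ligation with chromatin
immunoprecipitation, enriching long-range contacts anchored at the binding
sites of a targeted protein. That enrichment is the point of the assay, but
it also makes Hi-C reproducibility measures — built for balanced, symmetric
contact matrices — unreliable on HP data: ChIP efficiency varies between
samples, and only bin pairs touching a peak ("anchor") carry signal. This
package quantifies the similarity of two HP samples with a metric designed
around that structure, for anyone who needs to decide whether two libraries
are replicates, whether samples cluster by cell type, or how far a library
can be downsampled before it stops being informative.

## Method

1. **Normalization.** Non-zero long-range (> 1 Kb) bin-pair counts are
   modeled with a zero-truncated Poisson (ZTP) regression,

   log μ<sub>ij</sub> = β₀ + β₁·FL<sub>ij</sub> + β₂·GC<sub>ij</sub> + β₃·MS<sub>ij</sub> + β₄·IP<sub>ij</sub>,

   where each covariate is log(x<sub>i</sub>·x<sub>j</sub>) of the two bins'
   effective fragment length, GC content, mappability, and short-range
   (≤ 1 Kb) read count — the last being a proxy for ChIP efficiency.
   Models are fitted separately per chromosome for the AND pairs (both
   bins in anchors) and XOR pairs (exactly one bin in an anchor); NOT
   pairs are discarded. The normalized contact value is
   log₂(1 + observed/fitted).

2. **Anchor-by-offset matrix.** Normalized values fill an N × m matrix:
   N union anchors across all samples as rows, signed bin offsets
   −m/2…−1, 1…m/2 as columns, with m = 2·(binning distance)/(resolution)
   (m = 400 at 5 Kb, 200 at 10 Kb for the default 1 Mb distance). Rows
   are smoothed with a 1D moving average of half-width *d*, tuned by
   repeated 25% subsampling until an extra unit of smoothing improves
   the score by less than 1%.

3. **Stratified weighted correlation.** For each offset stratum k
   (pooling columns −k and +k, dropping positions zero in both samples),
   compute the Pearson correlation r<sub>k</sub>; combine with weights
   w<sub>k</sub> ∝ N<sub>k</sub>·σ(a′<sub>k</sub>)·σ(b′<sub>k</sub>).
   The reproducibility score Σ<sub>k</sub> r<sub>k</sub> w<sub>k</sub> ∈ [−1, 1]
   is averaged over chromosomes.

Supporting machinery: multinomial downsampling to a fraction of the
original depth, pseudo-replicate generation by pooling two replicates and
splitting each count Binomial(c, ½), a similarity-based silhouette for
judging how well scores cluster samples by condition, and a synthetic-study
generator that emulates the whole data model (features, peaks with a
controlled anchor Jaccard overlap, ZTP counts with distance decay and
condition-specific loops) so every stage runs without external data.

## Worked example

```r
library(hprep)
cfg <- sim_config(n_bins = 800, n_chroms = 1, depth = 5e4,
                  anchor_density = 0.08, seed = 11)
study <- simulate_study(cfg)          # 2 conditions x 2 replicates
res <- run_study(study, d = "tune", seed = 11)
res$d
#> [1] 4
round(res$scores, 3)
#>            cond1_rep1 cond1_rep2 cond2_rep1 cond2_rep2
#> cond1_rep1      1.000      0.853     -0.256     -0.303
#> cond1_rep2      0.853      1.000     -0.236     -0.295
#> cond2_rep1     -0.256     -0.236      1.000      0.812
#> cond2_rep2     -0.303     -0.295      0.812      1.000
silhouette_mean(minmax_scale(res$scores), study$labels)$mean
#> [1] 0.9733058
```

Replicates of the same condition score high (0.85, 0.81); samples from
different conditions — different anchor sets, different loop structure —
score near or below zero. The tuned smoothing half-width is 4 bins, and
the near-1 silhouette says the score matrix cleanly separates the two
conditions. `res$fits` holds the per-chromosome/per-class regression
summaries (coefficients, log-likelihood, AIC/BIC).

The same workflow runs from the shell against on-disk studies:

```sh
Rscript inst/cli/hprep.R simulate  --out demo --seed 5 --n-bins 600 --n-chroms 1 --depth 40000
Rscript inst/cli/hprep.R normalize --dir demo
Rscript inst/cli/hprep.R compare   --dir demo
```

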