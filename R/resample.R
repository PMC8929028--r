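# Depth manipulation: multinomial downsampling of contact tables and
# pseudo-replicate generation by pooling + binomial splitting.

#' Derive a stable sub-seed
#'
#' Deterministic 31-bit hash of a master seed and string labels, so that
#' every (sample, chromosome, class) file gets its own reproducible RNG
#' stream and adding a sample never perturbs another's draws.
#'
#' @param master Non-negative integer master seed.
#' @param ... Character/numeric labels (e.g. sample id, chrom, class).
#' @return An integer in \[0, 2^31 - 1).
#' @export
derive_seed <- function(master, ...) {
  s <- paste(c(master, ...), collapse = "\r")
  h <- 0
  for (v in utf8ToInt(s)) h <- (h * 31 + v) %% 2147483647
  as.integer(h)
}

#' Multinomial downsampling of a contact table
#'
#' Reduces a file's total count `n` to `floor(n * factor)` by drawing the
#' per-pair counts from `Multinomial(floor(n * factor), v / n)` where `v`
#' is the original count vector, separately for every (chromosome, class)
#' group. Pairs drawn to zero are removed; covariates are untouched.
#'
#' @param pairs Bin-pair table (columns `chrom, class, count`, ...).
#' @param factor Downsampling coefficient in (0, 1\].
#' @param seed Master seed; per-group streams derive from
#'   `(seed, sample_id, chrom, class)`.
#' @param sample_id Label entering the sub-seed derivation.
#' @return The downsampled bin-pair table (zero-count rows dropped).
#' @export
downsample_pairs <- function(pairs, factor, seed = 1L, sample_id = "") {
  if (!is.numeric(factor) || factor <= 0 || factor > 1)
    stop("`factor` must lie in (0, 1]")
  p <- data.table::as.data.table(pairs)
  groups <- unique(p[, .(chrom, class)])
  out <- vector("list", nrow(groups))
  for (g in seq_len(nrow(groups))) {
    sub <- p[chrom == groups$chrom[g] & class == groups$class[g]]
    n <- sum(sub$count)
    size <- floor(n * factor)
    set.seed(derive_seed(seed, sample_id, groups$chrom[g], groups$class[g]))
    sub$count <- as.integer(rmultinom(1, size = size, prob = sub$count / n))
    out[[g]] <- sub[count > 0]
  }
  res <- data.table::rbindlist(out)
  data.table::setorder(res, chrom, bin1, bin2)
  res[]
}

#' Pseudo-replicates by pooling and binomial splitting
#'
#' Pools two same-condition samples (summing counts over the union of
#' their bin pairs) and randomly re-partitions each pooled count c into
#' `Binomial(c, 0.5)` and its complement, yielding a pair of artificial
#' samples whose similarity upper-bounds what real replicates can reach.
#' Counts are conserved pair-wise; zero outcomes are dropped from each
#' pseudo table. Covariates are taken from whichever input carried the
#' pair (they agree when both did, being per-bin properties).
#'
#' @param pairsA,pairsB Bin-pair tables of the two replicates.
#' @param seed Integer seed.
#' @return A list of two bin-pair tables, `pseudoA` and `pseudoB`.
#' @export
make_pseudo_replicates <- function(pairsA, pairsB, seed = 1L) {
  a <- data.table::as.data.table(pairsA)
  b <- data.table::as.data.table(pairsB)
  keycols <- c("chrom", "bin1", "bin2", "class")
  covs <- setdiff(names(a), c(keycols, "count"))
  pooled <- data.table::rbindlist(list(a, b))[
    , c(list(count = sum(count)),
        lapply(.SD, data.table::first)),
    by = keycols, .SDcols = covs]
  set.seed(derive_seed(seed, "pseudo"))
  ca <- rbinom(nrow(pooled), size = pooled$count, prob = 0.5)
  mk <- function(cnt) {
    out <- data.table::copy(pooled)[, count := as.integer(cnt)]
    data.table::setcolorder(out, c(keycols, "count"))
    out <- out[count > 0]
    data.table::setorder(out, chrom, bin1, bin2)
    out[]
  }
  list(pseudoA = mk(ca), pseudoB = mk(pooled$count - ca))
}
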