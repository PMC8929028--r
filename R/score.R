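# Distance-stratified weighted Pearson correlation between two
# anchor-by-offset matrices. Stratum k pools the two columns at signed
# offsets -k and +k (each of length N), drops positions that are zero in
# both samples, and correlates what remains; strata are combined with
# weights proportional to N_k * sd(a'_k) * sd(b'_k) (population moments).

#' Extract one distance stratum from a matrix pair
#'
#' @param matA,matB `anchor_offset_matrix` objects built on the same
#'   union anchor set and geometry.
#' @param k Stratum index, 1..m/2 (offset in bin widths).
#' @return A list with vectors `a`, `b` (length `N_k` after joint-zero
#'   removal) and `n` (`N_k`).
#' @export
extract_stratum <- function(matA, matB, k) {
  if (!identical(matA$anchors, matB$anchors) ||
      !identical(matA$offsets, matB$offsets))
    stop("matrices must share the union anchor set and offset grid; ",
         "build both on union_anchors()")
  m <- length(matA$offsets)
  if (k < 1 || k > m / 2) stop("stratum index k must be in 1..m/2")
  cols <- c(offset_to_col(-k, m), offset_to_col(k, m))
  a <- c(matA$values[, cols[1]], matA$values[, cols[2]])
  b <- c(matB$values[, cols[1]], matB$values[, cols[2]])
  keep <- !(a == 0 & b == 0)
  list(a = a[keep], b = b[keep], n = sum(keep))
}

pop_sd <- function(x) {
  n <- length(x)
  sqrt(sum(x^2) / n - (sum(x) / n)^2)
}

stratum_defined <- function(s) {
  s$n >= 2 && pop_sd(s$a) > 0 && pop_sd(s$b) > 0
}

#' Pearson correlation within one stratum
#'
#' Empirical (population-moment) Pearson correlation of the joint-zero-
#' filtered stratum vectors. Undefined (fewer than two positions, or a
#' zero-variance vector) strata return `NA` rather than erroring; they
#' are weighted 0 downstream.
#'
#' @param s A stratum as from [extract_stratum()].
#' @return Correlation in \[-1, 1\], or `NA_real_` when undefined.
#' @export
stratum_correlation <- function(s) {
  if (!stratum_defined(s)) return(NA_real_)
  n <- s$n
  num <- n * sum(s$a * s$b) - sum(s$a) * sum(s$b)
  den <- sqrt(n * sum(s$a^2) - sum(s$a)^2) * sqrt(n * sum(s$b^2) - sum(s$b)^2)
  max(-1, min(1, num / den))
}

#' Stratum weights
#'
#' `w_k` is proportional to `N_k * sd(a'_k) * sd(b'_k)` with population
#' standard deviations, normalized to sum to 1 over the defined strata;
#' larger and more variable strata carry more weight. Undefined strata
#' get weight 0 and are excluded from the denominator.
#'
#' @param strata List of strata from [extract_stratum()].
#' @return Numeric weight vector summing to 1 (all zero when every
#'   stratum is undefined).
#' @export
stratum_weights <- function(strata) {
  raw <- vapply(strata, function(s) {
    if (!stratum_defined(s)) return(0)
    s$n * pop_sd(s$a) * pop_sd(s$b)
  }, numeric(1))
  tot <- sum(raw)
  if (tot == 0) return(raw)
  raw / tot
}

#' Reproducibility score between two samples on one chromosome
#'
#' Smooths both anchor-by-offset matrices with window half-width `d`,
#' computes the per-stratum correlations `r_k` and weights `w_k` for
#' `k = 1..m/2`, and returns the weighted sum `sum(r_k * w_k)`, a
#' correlation-like score in \[-1, 1\] symmetric in its arguments.
#'
#' @param matA,matB `anchor_offset_matrix` objects on the shared union
#'   anchor set.
#' @param d Smoothing window half-width (0 = no smoothing).
#' @return The score, or `NA_real_` when every stratum is undefined.
#' @export
reproducibility_score <- function(matA, matB, d = 0L) {
  sA <- smooth_matrix(matA, d)
  sB <- smooth_matrix(matB, d)
  K <- length(matA$offsets) / 2
  strata <- lapply(seq_len(K), function(k) extract_stratum(sA, sB, k))
  w <- stratum_weights(strata)
  if (sum(w) == 0) return(NA_real_)
  r <- vapply(strata, stratum_correlation, numeric(1))
  r[w == 0] <- 0
  sum(r * w)
}

#' Genome-wide reproducibility between two samples
#'
#' Scores every chromosome separately and reports the unweighted
#' arithmetic mean (and standard deviation) over the chromosomes with a
#' defined score.
#'
#' @param matsA,matsB Named lists of `anchor_offset_matrix` objects (one
#'   per chromosome, same names) for the two samples.
#' @param d Smoothing window half-width.
#' @return A list: `per_chrom` (named numeric), `mean`, `sd`.
#' @export
genome_score <- function(matsA, matsB, d = 0L) {
  chroms <- names(matsA)
  if (!identical(sort(chroms), sort(names(matsB))))
    stop("samples cover different chromosomes")
  per <- vapply(chroms, function(ch)
    reproducibility_score(matsA[[ch]], matsB[[ch]], d), numeric(1))
  ok <- !is.na(per)
  if (!any(ok)) return(list(per_chrom = per, mean = NA_real_, sd = NA_real_))
  if (!all(ok))
    warning("score undefined on ", sum(!ok), " chromosome(s); mean over the rest")
  list(per_chrom = per,
       mean = mean(per[ok]),
       sd = if (sum(ok) > 1) sd(per[ok]) else 0)
}

#' Tune the smoothing window by repeated subsampling
#'
#' For each candidate `d = 0, 1, 2, ...`: draw ten independent 25%
#' subsamples of sample A's non-zero matrix cells (without replacement),
#' zero the remaining cells, restrict sample B to the same positions,
#' score each subsampled pair at smoothing `d`, and average the ten
#' scores. Iterate `d` until the average at `d + 1` improves on `d` by
#' less than one percent, and return that `d`. Tuning should use a
#' dissimilar pair (e.g. non-replicates) so the score has room to move.
#'
#' @param matsA,matsB Named per-chromosome matrix lists for the two
#'   samples (as in [genome_score()]).
#' @param seed Integer seed; the same seed reproduces the same `d`.
#' @param frac Subsampled fraction of non-zero cells (default 0.25).
#' @param reps Number of subsamples per candidate (default 10).
#' @param max_d Search cap (default `m/2 - 1`).
#' @return A list: `d` (selected window), `trajectory` (`data.table` of
#'   candidate `d` and mean subsampled score).
#' @export
tune_smoothing <- function(matsA, matsB, seed = 1L, frac = 0.25,
                           reps = 10L, max_d = NULL) {
  m <- length(matsA[[1]]$offsets)
  if (is.null(max_d)) max_d <- m / 2 - 1
  nz <- lapply(matsA, function(x) which(x$values != 0))
  if (!any(lengths(nz) > 0)) stop("sample A has no non-zero cells")

  score_at <- function(d, rep_seed) {
    set.seed(rep_seed)
    per_rep <- numeric(reps)
    for (r in seq_len(reps)) {
      subA <- matsA; subB <- matsB
      for (ch in names(matsA)) {
        idx <- nz[[ch]]
        take <- sort(sample(idx, size = floor(length(idx) * frac)))
        vA <- matsA[[ch]]$values; vB <- matsB[[ch]]$values
        keepA <- matrix(0, nrow(vA), ncol(vA)); keepA[take] <- vA[take]
        keepB <- matrix(0, nrow(vB), ncol(vB)); keepB[take] <- vB[take]
        subA[[ch]]$values <- keepA
        subB[[ch]]$values <- keepB
      }
      gs <- genome_score(subA, subB, d)
      per_rep[r] <- gs$mean
    }
    mean(per_rep)
  }

  traj <- data.table::data.table(d = integer(), mean_score = numeric())
  prev <- score_at(0L, seed)
  if (is.na(prev))
    stop("subsampled score undefined at d = 0; choose a different sample pair")
  traj <- rbind(traj, data.table::data.table(d = 0L, mean_score = prev))
  d <- 0L
  while (d < max_d) {
    nxt <- score_at(d + 1L, seed + d + 1L)
    traj <- rbind(traj, data.table::data.table(d = d + 1L, mean_score = nxt))
    if (is.na(nxt) || nxt < 1.01 * prev) break
    prev <- nxt
    d <- d + 1L
  }
  list(d = d, trajectory = traj)
}

#' Naive Pearson baseline on square contact matrices
#'
#' Flattens the upper triangle (diagonal excluded) of two square
#' contact matrices on a shared bin grid and returns their Pearson
#' correlation; the simplest whole-matrix comparator.
#'
#' @param matA_square,matB_square Square numeric matrices of equal
#'   dimension.
#' @return Correlation in \[-1, 1\], or `NA` when either vector has zero
#'   variance.
#' @export
naive_pearson <- function(matA_square, matB_square) {
  if (!all(dim(matA_square) == dim(matB_square)))
    stop("matrices must have identical dimensions")
  ut <- upper.tri(matA_square)
  a <- matA_square[ut]; b <- matB_square[ut]
  if (pop_sd(a) == 0 || pop_sd(b) == 0) return(NA_real_)
  stats::cor(a, b)
}

#' Score every sample pair of a study
#'
#' @param mats Named list (by sample) of named per-chromosome matrix
#'   lists, all built on the same union anchor set.
#' @param d Smoothing window half-width.
#' @return A list: `scores` (symmetric mean-score matrix, diagonal 1),
#'   `per_chrom` (long `data.table` of per-chromosome scores), `sd`
#'   (matrix of across-chromosome standard deviations).
#' @export
score_all_pairs <- function(mats, d = 0L) {
  ids <- names(mats)
  n <- length(ids)
  scores <- diag(1, n); dimnames(scores) <- list(ids, ids)
  sds <- matrix(0, n, n, dimnames = list(ids, ids))
  per <- list()
  if (n >= 2) {
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      gs <- genome_score(mats[[i]], mats[[j]], d)
      scores[i, j] <- scores[j, i] <- gs$mean
      sds[i, j] <- sds[j, i] <- gs$sd
      per[[length(per) + 1L]] <- data.table::data.table(
        sample_a = ids[i], sample_b = ids[j],
        chrom = names(gs$per_chrom), score = unname(gs$per_chrom))
    }
  }
  list(scores = scores,
       per_chrom = if (length(per)) data.table::rbindlist(per) else NULL,
       sd = sds)
}
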