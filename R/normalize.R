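#' Classify bin pairs as AND / XOR / NOT
#'
#' A pair is AND when both bins lie in anchor bins (binned ChIP peaks),
#' XOR when exactly one does, NOT when neither does. NOT pairs carry no
#' protein-centric signal and are excluded from all downstream analysis;
#' they are returned so callers can count what was discarded.
#'
#' @param pairs Bin-pair table with `chrom, bin1, bin2` (any other
#'   columns carried through).
#' @param anchors An `anchor_set` at the same resolution.
#' @return A list with `data.table` elements `AND`, `XOR`, `NOT`; the
#'   first two carry an updated `class` column.
#' @export
classify_pairs <- function(pairs, anchors) {
  p <- data.table::as.data.table(pairs)
  anchor_keys <- unlist(lapply(names(anchors), function(ch)
    paste0(ch, ":", anchors[[ch]])))
  n_anchor_ends <- (paste0(p$chrom, ":", p$bin1) %in% anchor_keys) +
    (paste0(p$chrom, ":", p$bin2) %in% anchor_keys)
  out <- list(
    AND = p[n_anchor_ends == 2][, class := "AND"],
    XOR = p[n_anchor_ends == 1][, class := "XOR"],
    NOT = p[n_anchor_ends == 0][, class := "NOT"]
  )
  lapply(out, function(x) x[])
}

#' Split read pairs into short- and long-range
#'
#' Intra-chromosomal read pairs separated by at most 1 Kb are "short"
#' and contribute to the per-bin ChIP-efficiency proxy; pairs over 1 Kb
#' are the long-range contacts that enter the interaction analysis. The
#' 1,000 bp boundary itself is short.
#'
#' @param separations Non-negative bp separations.
#' @param threshold Boundary in bp (default 1000).
#' @return A list with logical-complement integer index vectors `short`
#'   and `long` into `separations`.
#' @export
split_short_long <- function(separations, threshold = 1000) {
  if (any(separations < 0)) stop("separations must be non-negative")
  list(short = which(separations <= threshold),
       long = which(separations > threshold))
}

#' Normalize bin-pair counts against fitted values
#'
#' The normalized contact value is `log2(1 + observed / fitted)`, so a
#' pair observed exactly at its model expectation scores 1 and enrichment
#' above expectation scores above 1.
#'
#' @param pairs Bin-pair table with `count` >= 1.
#' @param fitted Positive fitted values aligned with `pairs` rows.
#' @return `pairs` with columns `fitted` and `normalized` added.
#' @export
normalize_pairs <- function(pairs, fitted) {
  if (length(fitted) != nrow(pairs)) stop("fitted values misaligned with pairs")
  if (any(fitted <= 0)) stop("fitted values must be strictly positive")
  p <- data.table::as.data.table(pairs)
  p[, fitted := fitted]
  p[, normalized := log2(1 + count / fitted)]
  p[]
}

#' Normalize one sample end to end
#'
#' Fits the zero-truncated Poisson regression separately for the AND and
#' XOR sets of every chromosome (2 fits per chromosome), computes fitted
#' values, and combines the normalized AND and XOR pairs of all
#' chromosomes into one table. Chromosome/class cells with fewer than 50
#' pairs are skipped with a warning rather than fitted.
#'
#' @param pairs Bin-pair table for one sample, `class` column holding
#'   `"AND"`/`"XOR"`.
#' @param fitted_type Passed to [predict_fitted()].
#' @return A list: `normalized` (one combined `data.table` with
#'   `fitted`/`normalized` columns) and `fits` (a `data.table` model
#'   summary with beta, logLik, AIC, BIC per chromosome and class).
#' @export
normalize_sample <- function(pairs, fitted_type = "truncated") {
  p <- data.table::as.data.table(pairs)
  if (!all(p$class %in% c("AND", "XOR")))
    stop("normalize_sample expects AND/XOR pairs only (drop NOT pairs first)")
  groups <- unique(p[, .(chrom, class)])
  norm_list <- list()
  fit_list <- list()
  for (g in seq_len(nrow(groups))) {
    ch <- groups$chrom[g]; cl <- groups$class[g]
    sub <- p[chrom == ch & class == cl]
    if (nrow(sub) < 50L) {
      warning("skipping ", ch, " ", cl, ": only ", nrow(sub), " pairs (< 50)")
      next
    }
    fit <- fit_ztp(sub)
    sub <- normalize_pairs(sub, predict_fitted(fit, sub, type = fitted_type))
    norm_list[[length(norm_list) + 1L]] <- sub
    fit_list[[length(fit_list) + 1L]] <- data.table::data.table(
      chrom = ch, class = cl, n_obs = fit$n_obs,
      beta0 = fit$beta[1], beta_fl = fit$beta[2], beta_gc = fit$beta[3],
      beta_ms = fit$beta[4], beta_ip = fit$beta[5],
      loglik = fit$loglik, aic = fit$aic, bic = fit$bic,
      iterations = fit$iterations)
  }
  if (!length(norm_list)) stop("no chromosome/class cell had enough pairs to fit")
  normalized <- data.table::rbindlist(norm_list)
  data.table::setorder(normalized, chrom, bin1, bin2)
  list(normalized = normalized, fits = data.table::rbindlist(fit_list))
}
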