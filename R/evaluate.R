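# Clustering-quality evaluation of a pairwise score matrix: min-max
# scaling to [0, 1] followed by a similarity-oriented silhouette.

#' Min-max scale a score matrix to \[0, 1\]
#'
#' Affine map `(x - min) / (max - min)` using the off-diagonal minimum
#' and maximum (self-similarity on the diagonal would otherwise anchor
#' the maximum and distort the scale); the diagonal is set to 1. The
#' silhouette requires ratio-scale similarities, which raw correlations
#' are not — hence this standardization.
#'
#' @param scores Symmetric score matrix with sample dimnames.
#' @return The scaled matrix, off-diagonal range exactly \[0, 1\].
#' @export
minmax_scale <- function(scores) {
  scores <- as.matrix(scores)
  off <- scores[row(scores) != col(scores)]
  lo <- min(off); hi <- max(off)
  if (hi <= lo) stop("constant off-diagonal score matrix cannot be scaled")
  out <- (scores - lo) / (hi - lo)
  diag(out) <- 1
  out
}

#' Mean silhouette of a labeled similarity matrix
#'
#' For sample i in cluster A, let `a(i)` be its mean similarity to the
#' other members of A and `b(i)` the largest mean similarity to any
#' other cluster; then `s(i) = (a(i) - b(i)) / max(a(i), b(i))`. With
#' similarities (not distances), well-separated clusters push `s(i)`
#' toward 1. Samples in singleton clusters get `s(i) = 0`. Returns the
#' average over all samples.
#'
#' @param scores Similarity matrix in \[0, 1\] (see [minmax_scale()])
#'   with sample dimnames.
#' @param labels Cluster labels, either named by sample or in matrix
#'   order.
#' @return A list: `mean` (average silhouette) and `s` (named per-sample
#'   values in \[-1, 1\]).
#' @export
silhouette_mean <- function(scores, labels) {
  scores <- as.matrix(scores)
  ids <- rownames(scores)
  if (!is.null(names(labels))) labels <- labels[ids]
  labels <- as.character(labels)
  if (length(labels) != nrow(scores) || anyNA(labels))
    stop("every sample needs a cluster label")
  if (length(unique(labels)) < 2)
    stop("silhouette needs at least two clusters")
  s <- vapply(seq_along(ids), function(i) {
    own <- which(labels == labels[i]); own <- setdiff(own, i)
    if (length(own) == 0) return(0)  # singleton cluster
    a_i <- mean(scores[i, own])
    others <- setdiff(unique(labels), labels[i])
    b_i <- max(vapply(others, function(cl)
      mean(scores[i, labels == cl]), numeric(1)))
    (a_i - b_i) / max(a_i, b_i)
  }, numeric(1))
  names(s) <- ids
  list(mean = mean(s), s = s)
}
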