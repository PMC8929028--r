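# Anchor-by-offset matrices: rows are union anchor bins, columns are the
# signed offsets {-m/2, ..., -1, 1, ..., m/2} in bin widths. Column index
# arithmetic treats -1 and +1 as adjacent (there is no offset-0 column).

offset_to_col <- function(offset, m) {
  ifelse(offset < 0, offset + m / 2 + 1, offset + m / 2)
}

col_to_offset <- function(col, m) {
  ifelse(col <= m / 2, col - m / 2 - 1, col - m / 2)
}

#' Build the anchor-by-offset matrix for one chromosome
#'
#' Arranges normalized AND/XOR contact values in an `N x m` grid: row i
#' is the i-th union anchor bin, column j the bin `j` bin widths away
#' (signed offsets up to the binning distance). An XOR pair populates
#' one cell (from its single anchor end); an AND pair populates two, one
#' per anchor row, at opposite-signed offsets. Unwritten cells are 0.
#' Pairs farther apart than the binning distance are dropped.
#'
#' @param normalized Normalized pair table for one chromosome (columns
#'   `chrom, bin1, bin2, class, normalized`).
#' @param union_anchors An `anchor_set` holding the study-wide union of
#'   anchors (pairs whose anchor end is missing from it are an error).
#' @param config A `study_config`.
#' @param chrom Chromosome to build; defaults to the single chromosome
#'   present in `normalized`.
#' @return An `anchor_offset_matrix`: list with `chrom`, `anchors`,
#'   `offsets`, `values` (N x m), `resolution`, `smoothed_with`.
#' @export
build_matrix <- function(normalized, union_anchors, config, chrom = NULL) {
  p <- data.table::as.data.table(normalized)
  if (is.null(chrom)) {
    chrom <- unique(p$chrom)
    if (length(chrom) != 1L)
      stop("`normalized` spans several chromosomes; pass `chrom`")
  }
  p <- p[p$chrom == chrom]
  anchors <- union_anchors[[chrom]]
  if (is.null(anchors)) anchors <- numeric()
  m <- config$m
  res <- config$resolution
  values <- matrix(0, nrow = length(anchors), ncol = m)
  if (nrow(p)) {
    if (!all(p$class %in% c("AND", "XOR")))
      stop("matrix accepts AND/XOR pairs only")
    k <- (p$bin2 - p$bin1) / res
    keep <- k <= m / 2
    p <- p[keep]; k <- k[keep]
    row1 <- match(p$bin1, anchors)   # bin1 as anchor, partner at +k
    row2 <- match(p$bin2, anchors)   # bin2 as anchor, partner at -k
    if (any(is.na(row1) & is.na(row2)))
      stop("pair with neither end in the union anchor set ",
           "(should have been NOT-classified)")
    w1 <- !is.na(row1)
    w2 <- !is.na(row2)
    values[cbind(row1[w1], offset_to_col(k[w1], m))] <- p$normalized[w1]
    values[cbind(row2[w2], offset_to_col(-k[w2], m))] <- p$normalized[w2]
  }
  structure(list(
    chrom = chrom,
    anchors = anchors,
    offsets = c(-(m / 2):-1, 1:(m / 2)),
    values = values,
    resolution = res,
    smoothed_with = "raw"
  ), class = "anchor_offset_matrix")
}

#' @export
print.anchor_offset_matrix <- function(x, ...) {
  cat("anchor_offset_matrix ", x$chrom, ": ", length(x$anchors), " anchors x ",
      length(x$offsets), " offsets (resolution ", x$resolution,
      " bp, smoothing ", format(x$smoothed_with), ")\n", sep = "")
  invisible(x)
}

#' Smooth an anchor-by-offset matrix
#'
#' 1D moving average along each row: every cell becomes the mean of the
#' `2d + 1` cells within `d` columns of it, where columns falling outside
#' the matrix contribute 0 and the divisor stays `2d + 1` (values near
#' the +/- binning-distance edges therefore shrink). The window runs over
#' the column index, so offsets -1 and +1 are adjacent. `d = 0` is the
#' identity.
#'
#' @param mat An `anchor_offset_matrix`.
#' @param d Non-negative integer window half-width, in bins.
#' @return The smoothed `anchor_offset_matrix` (`smoothed_with = d`).
#' @export
smooth_matrix <- function(mat, d) {
  stopifnot(inherits(mat, "anchor_offset_matrix"))
  if (d < 0 || d %% 1 != 0) stop("`d` must be a non-negative integer")
  m <- ncol(mat$values)
  if (d >= m) stop("`d` must be smaller than the number of columns (", m, ")")
  out <- mat
  if (d > 0 && nrow(mat$values) > 0) {
    padded <- cbind(matrix(0, nrow(mat$values), d), mat$values,
                    matrix(0, nrow(mat$values), d))
    cs <- cbind(0, t(apply(padded, 1, cumsum)))
    out$values <- (cs[, (2 * d + 2):(m + 2 * d + 1), drop = FALSE] -
                     cs[, 1:m, drop = FALSE]) / (2 * d + 1)
  }
  out$smoothed_with <- as.integer(d)
  out
}
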