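#' Read a bin-pair contact table
#'
#' Reads one MAPS-style long-range contact file: tab-delimited with a
#' header, columns `chr  bin1  bin2  count  fl  gc  ms  ip`. Bin starts
#' are 0-based and must be multiples of the analysis resolution; bins are
#' half-open `[start, start + resolution)`. The pair covariates are the
#' `log(x_i * x_j)` products of per-bin fragment length, GC, mappability
#' and ChIP-enrichment features. Rows with a zero count are dropped:
#' downstream the regression models only the non-zero contacts.
#'
#' @param path Path to a tab-delimited file.
#' @param pair_class `"AND"` or `"XOR"`, recorded on every row.
#' @param resolution Bin size in bp.
#' @return A `data.table` with columns `chrom, bin1, bin2, count, fl, gc,
#'   ms, ip, class`, sorted by `(chrom, bin1, bin2)`.
#' @export
read_bin_pairs <- function(path, pair_class = c("AND", "XOR"), resolution) {
  pair_class <- match.arg(pair_class)
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = list(character = 1))
  need <- c("chr", "bin1", "bin2", "count", "fl", "gc", "ms", "ip")
  if ("chrom" %in% names(dt)) data.table::setnames(dt, "chrom", "chr")
  if (!all(need %in% names(dt)))
    stop("bin-pair file ", path, " is missing columns: ",
         paste(setdiff(need, names(dt)), collapse = ", "))
  dt <- dt[, need, with = FALSE]
  data.table::setnames(dt, "chr", "chrom")
  num_cols <- c("bin1", "bin2", "count", "fl", "gc", "ms", "ip")
  vals <- as.matrix(dt[, num_cols, with = FALSE])
  if (!is.numeric(vals)) stop("non-numeric field(s) in ", path)
  bad <- which(rowSums(!is.finite(vals)) > 0)
  if (length(bad))
    stop("malformed row(s) in ", path, " at data line(s): ",
         paste(head(bad, 5), collapse = ", "))
  if (any(dt$bin1 %% resolution != 0 | dt$bin2 %% resolution != 0)) {
    i <- which(dt$bin1 %% resolution != 0 | dt$bin2 %% resolution != 0)[1]
    stop("bin start not a multiple of resolution ", resolution,
         " at data line ", i, " in ", path)
  }
  if (any(dt$count < 0))
    stop("negative count at data line ", which(dt$count < 0)[1], " in ", path)
  if (any(dt$bin1 >= dt$bin2))
    stop("bin1 must be < bin2 (intra-chromosomal distinct bins) in ", path)
  dt <- dt[count > 0]
  dt[, count := as.integer(count)]
  dt[, class := pair_class]
  data.table::setorder(dt, chrom, bin1, bin2)
  dt[]
}

#' Write a bin-pair contact table
#'
#' Inverse of [read_bin_pairs()]; emits the `chr bin1 bin2 count fl gc ms
#' ip` dialect (the `class` column, if present, is not written — the class
#' is carried by the file's identity).
#'
#' @param pairs A bin-pair `data.table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bin_pairs <- function(pairs, path) {
  out <- data.table::as.data.table(pairs)[, .(chr = chrom, bin1, bin2, count, fl, gc, ms, ip)]
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}

#' Read a per-bin feature table
#'
#' Tab-delimited with header `chr  bin_start  effective_length  gc
#' mappability  short_count`. All features must be strictly positive so
#' that the pair covariate `log(x_i * x_j)` is finite; `short_count` is
#' the short-range (<= 1 Kb) read count used as the ChIP-efficiency
#' proxy.
#'
#' @param path Path to a tab-delimited file.
#' @return A `data.table` keyed by `(chrom, bin_start)`.
#' @export
read_bin_features <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = list(character = 1))
  if ("chrom" %in% names(dt)) data.table::setnames(dt, "chrom", "chr")
  need <- c("chr", "bin_start", "effective_length", "gc", "mappability", "short_count")
  if (!all(need %in% names(dt)))
    stop("bin-feature file ", path, " is missing columns: ",
         paste(setdiff(need, names(dt)), collapse = ", "))
  data.table::setnames(dt, "chr", "chrom")
  feat <- c("effective_length", "gc", "mappability", "short_count")
  if (any(as.matrix(dt[, feat, with = FALSE]) <= 0))
    stop("bin features must be strictly positive (log(x_i * x_j) must be finite)")
  if (anyDuplicated(dt[, .(chrom, bin_start)]))
    stop("duplicate (chrom, bin_start) rows in ", path)
  data.table::setkey(dt, chrom, bin_start)
  dt[]
}

#' Attach pair covariates from per-bin features
#'
#' Convenience path when bin-pair tables carry raw counts only: computes
#' the pair covariates `fl`, `gc`, `ms`, `ip` as `log(x_i * x_j)` of the
#' two bins' features.
#'
#' @param pairs `data.table` with `chrom, bin1, bin2, count` (a `class`
#'   column is carried through).
#' @param features A per-bin feature table as from [read_bin_features()].
#' @return `pairs` with covariate columns added.
#' @export
join_features <- function(pairs, features) {
  p <- data.table::as.data.table(pairs)
  f <- data.table::as.data.table(features)
  lk <- function(bins, col) {
    i <- f[p[, .(chrom, bin_start = bins)], on = c("chrom", "bin_start"), which = TRUE]
    if (anyNA(i)) stop("bin(s) absent from the feature table")
    f[[col]][i]
  }
  p[, fl := log(lk(bin1, "effective_length") * lk(bin2, "effective_length"))]
  p[, gc := log(lk(bin1, "gc") * lk(bin2, "gc"))]
  p[, ms := log(lk(bin1, "mappability") * lk(bin2, "mappability"))]
  p[, ip := log(lk(bin1, "short_count") * lk(bin2, "short_count"))]
  p[]
}

#' Bin ChIP-Seq peaks into anchor bins
#'
#' Reads a BED/narrowPeak file (0-based half-open intervals; only the
#' first three columns are consulted) and assigns each peak to every
#' analysis-resolution bin it overlaps: a peak spanning a bin boundary
#' contributes all bins it spans.
#'
#' @param path Path to a BED3+/narrowPeak file (no header).
#' @param resolution Bin size in bp.
#' @return An `anchor_set`: a named list mapping chromosome to a sorted
#'   vector of unique 0-based bin starts.
#' @export
read_peaks_to_anchors <- function(path, resolution) {
  bed <- data.table::fread(path, sep = "\t", header = FALSE,
                           select = 1:3, col.names = c("chrom", "start", "end"),
                           colClasses = list(character = 1))
  peaks_to_anchors(bed, resolution)
}

#' @rdname read_peaks_to_anchors
#' @param peaks A data.frame with columns `chrom, start, end` (0-based
#'   half-open), as an in-memory alternative to a BED file.
#' @export
peaks_to_anchors <- function(peaks, resolution) {
  bed <- data.table::as.data.table(peaks)
  if (any(bed$end <= bed$start))
    stop("invalid peak interval: end <= start (BED is 0-based half-open)")
  per_peak <- bed[, {
    first <- as.numeric(start[1] %/% resolution) * resolution
    last <- as.numeric((end[1] - 1) %/% resolution) * resolution
    .(bin = seq(first, last, by = resolution))
  }, by = .(chrom, start, end)]
  sets <- lapply(split(per_peak$bin, per_peak$chrom), function(b) sort(unique(b)))
  as_anchor_set(sets)
}

as_anchor_set <- function(x) {
  x <- lapply(x, function(b) sort(unique(as.numeric(b))))
  x <- x[order(names(x))]
  structure(x, class = "anchor_set")
}

#' @export
print.anchor_set <- function(x, ...) {
  cat("anchor_set:", sum(lengths(x)), "anchor bins on",
      length(x), "chromosome(s)\n")
  invisible(x)
}

#' Union of anchor sets
#'
#' The per-chromosome sorted union over samples; its cardinality N defines
#' the row count of the anchor-by-offset matrix.
#'
#' @param anchor_sets A list of `anchor_set` objects.
#' @return An `anchor_set`.
#' @export
union_anchors <- function(anchor_sets) {
  if (length(anchor_sets) == 0) stop("need at least one anchor set")
  chroms <- unique(unlist(lapply(anchor_sets, names)))
  as_anchor_set(setNames(lapply(chroms, function(ch) {
    sort(unique(unlist(lapply(anchor_sets, function(s) s[[ch]]))))
  }), chroms))
}

#' Jaccard index between two anchor sets
#'
#' Intersection over union of the genome-wide anchor bin sets; quantifies
#' 1D peak sharing between conditions.
#'
#' @param a,b `anchor_set` objects at the same resolution.
#' @return A number in \[0, 1\].
#' @export
anchor_jaccard <- function(a, b) {
  key <- function(s) unlist(lapply(names(s), function(ch) paste0(ch, ":", s[[ch]])))
  ka <- key(a); kb <- key(b)
  length(intersect(ka, kb)) / length(union(ka, kb))
}

#' Write / read an anchor list
#'
#' Tab-delimited `chr  bin_start`, the binned-peak anchor list emitted by
#' the normalization step.
#'
#' @param anchors An `anchor_set`.
#' @param path File path.
#' @return For the writer, `path` invisibly; for the reader, an
#'   `anchor_set`.
#' @export
write_anchor_set <- function(anchors, path) {
  dt <- data.table::rbindlist(lapply(names(anchors), function(ch)
    data.table::data.table(chr = ch, bin_start = anchors[[ch]])))
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' @rdname write_anchor_set
#' @export
read_anchor_set <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = list(character = 1))
  as_anchor_set(split(dt$bin_start, dt$chr))
}

#' Write / read a pairwise score matrix
#'
#' Tab-delimited, sample identifiers as both header row and first column.
#' Values round-trip to 6 decimal places.
#'
#' @param scores A symmetric numeric matrix with identical row and column
#'   names (sample identifiers).
#' @param path File path.
#' @return For the writer, `path` invisibly; for the reader, a symmetric
#'   matrix.
#' @export
write_score_matrix <- function(scores, path) {
  scores <- as.matrix(scores)
  if (is.null(rownames(scores)) || is.null(colnames(scores)))
    stop("score matrix must carry sample identifiers as dimnames")
  if (max(abs(scores - t(scores)), na.rm = TRUE) > 1e-9)
    stop("score matrix is not symmetric")
  dt <- data.table::data.table(sample = rownames(scores))
  for (j in colnames(scores)) dt[[j]] <- sprintf("%.6f", scores[, j])
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' @rdname write_score_matrix
#' @export
read_score_matrix <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE)
  if (names(dt)[1] != "sample")
    stop("score-matrix file ", path, " is missing its header")
  ids <- as.character(dt$sample)
  m <- as.matrix(dt[, -1, with = FALSE])
  if (!identical(colnames(m), ids))
    stop("score-matrix header and first column disagree in ", path)
  rownames(m) <- ids
  storage.mode(m) <- "double"
  m
}
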