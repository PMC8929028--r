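# Independent oracles and tiny fixture builders shared across tests.
# Each oracle is written as directly as possible (loops, no shared code
# with the package) so it can stand as a second opinion.

# Hand-made anchor-by-offset matrix with arbitrary values.
toy_matrix <- function(values, resolution = 10000, chrom = "chr1") {
  m <- ncol(values)
  structure(list(
    chrom = chrom,
    anchors = (seq_len(nrow(values)) - 1) * resolution,
    offsets = c(-(m / 2):-1, 1:(m / 2)),
    values = values,
    resolution = resolution,
    smoothed_with = "raw"
  ), class = "anchor_offset_matrix")
}

random_toy_pair <- function(N, m, density = 0.5) {
  mk <- function() {
    v <- matrix(0, N, m)
    nz <- runif(N * m) < density
    v[nz] <- round(runif(sum(nz), 0.1, 3), 3)
    v
  }
  list(A = toy_matrix(mk()), B = toy_matrix(mk()))
}

# Monolithic reference implementation of smoothing + stratified weighted
# correlation, computed with plain loops and population moments.
oracle_score <- function(valA, valB, d) {
  m <- ncol(valA); N <- nrow(valA); K <- m / 2
  sm <- function(v) {
    out <- v * 0
    for (i in seq_len(N)) for (j in seq_len(m)) {
      lo <- max(1, j - d); hi <- min(m, j + d)
      out[i, j] <- sum(v[i, lo:hi]) / (2 * d + 1)
    }
    out
  }
  sA <- sm(valA); sB <- sm(valB)
  col_neg <- function(k) m / 2 - k + 1   # offset -k
  col_pos <- function(k) m / 2 + k       # offset +k
  rk <- numeric(K); num_w <- numeric(K)
  for (k in seq_len(K)) {
    a <- c(sA[, col_neg(k)], sA[, col_pos(k)])
    b <- c(sB[, col_neg(k)], sB[, col_pos(k)])
    keep <- !(a == 0 & b == 0)
    a <- a[keep]; b <- b[keep]; n <- length(a)
    if (n < 2) next
    sda <- sqrt(mean(a^2) - mean(a)^2)
    sdb <- sqrt(mean(b^2) - mean(b)^2)
    if (sda == 0 || sdb == 0) next
    rk[k] <- (mean(a * b) - mean(a) * mean(b)) / (sda * sdb)
    num_w[k] <- n * sda * sdb
  }
  if (sum(num_w) == 0) return(NA_real_)
  sum(rk * num_w / sum(num_w))
}

# Brute-force interval/bin overlap for the peak-binning rule.
oracle_peak_bins <- function(start, end, resolution, max_bin) {
  bins <- seq(0, max_bin, by = resolution)
  bins[pmax(bins, start) < pmin(bins + resolution, end)]
}

as_anchor_set_for_test <- function(x) {
  structure(lapply(x, function(b) sort(unique(as.numeric(b)))),
            class = "anchor_set")
}

# Minimal well-formed bin-pair table.
toy_pairs <- function(n = 60, chrom = "chr1", resolution = 10000,
                      class = "XOR", seed = 42) {
  set.seed(seed)
  b1 <- sort(sample.int(500, n, replace = TRUE)) * resolution
  data.table::data.table(
    chrom = chrom,
    bin1 = b1,
    bin2 = b1 + sample.int(50, n, replace = TRUE) * resolution,
    count = rpois(n, 4) + 1L,
    fl = rnorm(n), gc = rnorm(n), ms = rnorm(n), ip = rnorm(n),
    class = class)
}

small_sim_config <- function(seed, ...) {
  sim_config(n_bins = 800L, n_chroms = 1L, depth = 5e4,
             anchor_density = 0.08, seed = seed, ...)
}
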