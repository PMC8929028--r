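cfg10 <- study_config(resolution = 10000, chromosomes = "chr1",
                      samples = c("a", "b"))

norm_row <- function(bin1, bin2, value, class = "XOR") {
  data.table::data.table(chrom = "chr1", bin1 = bin1, bin2 = bin2,
                         class = class, normalized = value)
}

test_that("matrix width follows m = 2 * binning_distance / resolution", {
  expect_equal(study_config(resolution = 5000)$m, 400L)
  expect_equal(study_config(resolution = 10000)$m, 200L)
  ua <- as_anchor_set_for_test(list(chr1 = 50000))
  mat <- build_matrix(norm_row(50000, 70000, 1.5),
                      ua, study_config(resolution = 5000), chrom = "chr1")
  expect_equal(dim(mat$values), c(1L, 400L))
  expect_equal(mat$offsets, c(-200:-1, 1:200))
})

test_that("XOR pairs fill one cell, AND pairs fill both anchor rows", {
  ua <- as_anchor_set_for_test(list(chr1 = c(50000, 70000)))
  # XOR: anchor 50,000 sees partner at +4 bins
  mat <- build_matrix(norm_row(50000, 90000, 2.5), # 90,000 not an anchor
                      as_anchor_set_for_test(list(chr1 = 50000)), cfg10, "chr1")
  expect_equal(mat$values[1, which(mat$offsets == 4)], 2.5)
  expect_equal(sum(mat$values != 0), 1L)
  # AND: both rows, opposite-signed offsets
  mat <- build_matrix(norm_row(50000, 70000, 1.25, class = "AND"), ua, cfg10, "chr1")
  expect_equal(mat$values[1, which(mat$offsets == 2)], 1.25)
  expect_equal(mat$values[2, which(mat$offsets == -2)], 1.25)
  expect_equal(sum(mat$values != 0), 2L)
})

test_that("nonzero cells count #XOR + 2 * #AND and placement ignores input order", {
  ua <- as_anchor_set_for_test(list(chr1 = c(100000, 200000, 500000)))
  p <- rbind(norm_row(100000, 200000, 1.0, "AND"),
             norm_row(100000, 130000, 0.7),
             norm_row(480000, 500000, 0.9),
             norm_row(200000, 500000, 1.1, "AND"))
  m1 <- build_matrix(p, ua, cfg10, "chr1")
  expect_equal(sum(m1$values != 0), 2L + 2L * 2L)
  m2 <- build_matrix(p[c(3, 1, 4, 2)], ua, cfg10, "chr1")
  expect_equal(m1$values, m2$values)
})

test_that("pairs beyond the binning distance are dropped; orphans error", {
  ua <- as_anchor_set_for_test(list(chr1 = 0))
  mat <- build_matrix(norm_row(0, 2e6, 3), ua, cfg10, "chr1")
  expect_equal(sum(mat$values != 0), 0L)
  expect_error(build_matrix(norm_row(30000, 60000, 1), ua, cfg10, "chr1"),
               "NOT-classified")
})

test_that("smoothing follows the zero-padded 2d+1 window over column indices", {
  mat <- toy_matrix(matrix(c(0, 0, 6, 0, 0), nrow = 1))
  expect_equal(smooth_matrix(mat, 0)$values, mat$values)  # d = 0 identity
  expect_equal(smooth_matrix(mat, 1)$values,
               matrix(c(0, 2, 2, 2, 0), nrow = 1))
  ones <- toy_matrix(matrix(1, nrow = 1, ncol = 8))
  sm <- smooth_matrix(ones, 2)
  expect_equal(sm$values[1, 4], 1.0)       # interior
  expect_equal(sm$values[1, 1], 3 / 5)     # edge: zero-fill, divisor stays 5
  expect_error(smooth_matrix(ones, 8), "smaller")
  expect_error(smooth_matrix(ones, -1), "non-negative")
})

test_that("smoothing is linear and conserves interior row sums", {
  set.seed(4)
  X <- toy_matrix(matrix(runif(60), 5, 12))
  Y <- toy_matrix(matrix(runif(60), 5, 12))
  d <- 2
  lhs <- smooth_matrix(toy_matrix(3 * X$values + Y$values), d)$values
  rhs <- 3 * smooth_matrix(X, d)$values + smooth_matrix(Y, d)$values
  expect_equal(lhs, rhs, tolerance = 1e-12)
  # row with zero margin wider than d keeps its sum exactly
  v <- matrix(0, 1, 12); v[1, 4:9] <- runif(6)
  expect_equal(sum(smooth_matrix(toy_matrix(v), 2)$values), sum(v),
               tolerance = 1e-12)
})
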