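test_that("downsampling hits floor(n * factor) exactly and drops zeros", {
  p <- toy_pairs(80, seed = 2)
  n <- sum(p$count)
  for (f in c(1, 0.8, 0.5, 0.21)) for (s in c(1L, 99L)) {
    out <- downsample_pairs(p, f, seed = s, sample_id = "x")
    expect_equal(sum(out$count), floor(n * f))
    expect_true(all(out$count > 0))
  }
  # factor 1 keeps the total exactly (bins may still shuffle)
  expect_equal(sum(downsample_pairs(p, 1, seed = 5)$count), n)
  expect_error(downsample_pairs(p, 0, 1), "0, 1")
  expect_error(downsample_pairs(p, 1.2, 1), "0, 1")
})

test_that("downsampling is seed-reproducible and per-file independent", {
  p <- rbind(toy_pairs(60, chrom = "chr1", seed = 3),
             toy_pairs(60, chrom = "chr2", seed = 4))
  a <- downsample_pairs(p, 0.5, seed = 7, sample_id = "s1")
  b <- downsample_pairs(p, 0.5, seed = 7, sample_id = "s1")
  expect_identical(a, b)
  # chr1 draws do not change when chr2's content changes (distinct sub-seeds)
  p2 <- rbind(toy_pairs(60, chrom = "chr1", seed = 3),
              toy_pairs(90, chrom = "chr2", seed = 8))
  c1 <- downsample_pairs(p2, 0.5, seed = 7, sample_id = "s1")
  expect_equal(a[chrom == "chr1"], c1[chrom == "chr1"])
})

test_that("downsampled per-pair means match the multinomial moments", {
  p <- data.table::data.table(chrom = "chr1", bin1 = c(0, 10000, 20000),
                              bin2 = c(20000, 40000, 60000),
                              count = c(40L, 100L, 60L),
                              fl = 0, gc = 0, ms = 0, ip = 0, class = "XOR")
  f <- 0.5
  sums <- matrix(0, 200, 3)
  for (s in 1:200) {
    out <- downsample_pairs(p, f, seed = s)
    sums[s, ] <- out$count[match(p$bin1, out$bin1)]
  }
  emp <- colMeans(sums, na.rm = TRUE)
  expected <- p$count * f
  se <- sqrt(p$count * f * (1 - p$count / sum(p$count)) / 200)
  expect_true(all(abs(emp - expected) < 3 * pmax(se, 0.5)))
})

test_that("pseudo-replicates conserve pooled counts pairwise", {
  a <- toy_pairs(70, seed = 10)
  b <- toy_pairs(55, seed = 11)
  ps <- make_pseudo_replicates(a, b, seed = 3)
  pooled <- data.table::rbindlist(list(a, b))[
    , .(count = sum(count)), by = .(chrom, bin1, bin2, class)]
  recon <- data.table::rbindlist(list(ps$pseudoA, ps$pseudoB))[
    , .(count = sum(count)), by = .(chrom, bin1, bin2, class)]
  merged <- merge(pooled, recon, by = c("chrom", "bin1", "bin2", "class"))
  expect_equal(nrow(merged), nrow(pooled))
  expect_equal(merged$count.x, merged$count.y)
  expect_true(all(ps$pseudoA$count > 0) && all(ps$pseudoB$count > 0))
  # deterministic under the seed
  ps2 <- make_pseudo_replicates(a, b, seed = 3)
  expect_identical(ps, ps2)
})

test_that("binomial split halves counts on average", {
  a <- data.table::data.table(chrom = "chr1", bin1 = 0, bin2 = 20000,
                              count = 6L, fl = 0, gc = 0, ms = 0, ip = 0,
                              class = "XOR")
  b <- data.table::copy(a)[, count := 4L]  # pooled count 10
  draws <- vapply(1:1000, function(s) {
    pa <- make_pseudo_replicates(a, b, seed = s)$pseudoA
    if (nrow(pa)) pa$count else 0L
  }, integer(1))
  expect_lt(abs(mean(draws) - 5), 3 * sqrt(10 * 0.25 / 1000))
})
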