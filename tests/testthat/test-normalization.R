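test_that("pairs classify by anchor-end count into AND/XOR/NOT", {
  anchors <- peaks_to_anchors(
    data.frame(chrom = "chr1", start = c(10000, 30000), end = c(11000, 31000)),
    10000)
  p <- data.table::data.table(
    chrom = "chr1",
    bin1 = c(10000, 10000, 50000),
    bin2 = c(30000, 70000, 80000),
    count = 1L)
  cls <- classify_pairs(p, anchors)
  expect_equal(nrow(cls$AND), 1L)  # both ends anchors
  expect_equal(nrow(cls$XOR), 1L)
  expect_equal(nrow(cls$NOT), 1L)  # neither end an anchor: excluded downstream
  expect_equal(nrow(cls$AND) + nrow(cls$XOR) + nrow(cls$NOT), nrow(p))

  empty <- structure(list(), class = "anchor_set")
  cls0 <- classify_pairs(p, empty)
  expect_equal(nrow(cls0$NOT), nrow(p))
})

test_that("short/long split puts the 1 Kb boundary in short", {
  s <- split_short_long(c(1000, 1001, 50, 200000))
  expect_equal(s$short, c(1, 3))
  expect_equal(s$long, c(2, 4))
  expect_equal(lengths(split_short_long(numeric())), c(short = 0L, long = 0L))
  expect_error(split_short_long(-1), "non-negative")
})

test_that("ZTP log-likelihood matches its closed form and is a plain sum", {
  one <- data.table::data.table(count = 1L, fl = 0, gc = 0, ms = 0, ip = 0)
  # y = 1, mu = 1: log L = -1 - log(1 - exp(-1))
  expect_equal(ztp_loglik(rep(0, 5), one), -1 - log(1 - exp(-1)),
               tolerance = 1e-12)
  p <- toy_pairs(30)
  beta <- c(0.5, 0.1, -0.1, 0.2, 0.05)
  expect_equal(ztp_loglik(beta, p), ztp_loglik(beta, p[sample(.N)]))
  expect_equal(ztp_loglik(beta, rbind(p, p[7])),
               ztp_loglik(beta, p) + ztp_loglik(beta, p[7]))
  expect_error(ztp_loglik(c(800, 0, 0, 0, 0), one), "divergent")
})

test_that("fitted values are the zero-truncated mean", {
  fit <- structure(list(beta = rep(0, 5), converged = TRUE), class = "ztp_fit")
  one <- data.table::data.table(fl = 0, gc = 0, ms = 0, ip = 0)
  expect_equal(predict_fitted(fit, one), 1 / (1 - exp(-1)), tolerance = 1e-9)
  expect_equal(predict_fitted(fit, one, type = "mean"), 1)
  # truncation vanishes for large mu and always inflates the mean
  fit$beta <- c(log(30), 0, 0, 0, 0)
  expect_equal(predict_fitted(fit, one), 30, tolerance = 1e-9)
  for (mu in c(0.1, 0.5, 1, 3, 10)) {
    fit$beta <- c(log(mu), 0, 0, 0, 0)
    expect_gt(predict_fitted(fit, one), mu)
  }
  # monotone in mu
  mus <- exp(seq(-3, 3, by = 0.2))
  fitted <- sapply(mus, function(mu) {
    fit$beta <- c(log(mu), 0, 0, 0, 0); predict_fitted(fit, one)
  })
  expect_true(all(diff(fitted) > 0))
})

test_that("normalized value is log2(1 + observed/fitted)", {
  p <- data.table::data.table(chrom = "chr1", bin1 = 0, bin2 = 20000,
                              count = c(2L, 6L, 5L))
  out <- normalize_pairs(p, c(2, 2, 1.581977))
  expect_equal(out$normalized[1], 1)       # observed = fitted
  expect_equal(out$normalized[2], 2)       # observed = 3 * fitted
  expect_equal(out$normalized[3], 2.05676, tolerance = 1e-4)
  # monotone in observed at fixed fitted
  expect_true(all(diff(normalize_pairs(
    data.table::data.table(count = 1:10), rep(2, 10))$normalized) > 0))
  expect_error(normalize_pairs(p, c(1, -1, 1)), "positive")
})

test_that("ZTP fit maximizes the likelihood (generic-optimizer oracle)", {
  set.seed(21)
  for (i in 1:3) {
    beta <- c(runif(1, -0.5, 1.5), rnorm(4, sd = 0.3))
    p <- simulate_ztp_pairs(1500, beta, seed = 100 + i)
    fit <- fit_ztp(p)
    obj <- function(b) tryCatch(-ztp_loglik(b, p), error = function(e) 1e10)
    ref <- optim(rep(0, 5), obj, method = "BFGS",
                 control = list(maxit = 500, reltol = 1e-14))
    expect_lt(max(abs(fit$beta - ref$par)), 1e-5)
    expect_gte(fit$loglik, -ref$value - 1e-8)
  }
})

test_that("ZTP fit recovers simulation truth and honors the score equation", {
  beta <- c(1.0, 0.3, -0.2, 0.1, 0.5)
  p <- simulate_ztp_pairs(50000, beta, seed = 7)
  fit <- fit_ztp(p)
  expect_true(all(abs(fit$beta - beta) < 3 * fit$se))
  # intercept score equation: sum of truncated means equals sum of counts
  expect_equal(sum(predict_fitted(fit, p)), sum(p$count), tolerance = 1e-6)
  expect_equal(fit$aic, 10 - 2 * fit$loglik)
  expect_equal(fit$bic, 5 * log(fit$n_obs) - 2 * fit$loglik)
})

test_that("ZTP fit is invariant to record duplication and input order", {
  p <- simulate_ztp_pairs(400, c(0.8, 0.2, -0.1, 0, 0.3), seed = 5)
  f1 <- fit_ztp(p)
  f2 <- fit_ztp(rbind(p, p))
  expect_equal(f1$beta, f2$beta, tolerance = 1e-7)
  f3 <- fit_ztp(p[sample(.N)])
  expect_equal(f1$beta, f3$beta, tolerance = 1e-9)
})

test_that("degenerate designs are refused with clear diagnostics", {
  p <- toy_pairs(60)
  expect_error(fit_ztp(p[1:20]), "< 50")
  p2 <- data.table::copy(p)[, `:=`(fl = 0, gc = 0, ms = 0, ip = 0)]
  expect_error(fit_ztp(p2), "collinear")
  p3 <- data.table::copy(p)[, gc := 2 * fl]
  expect_error(fit_ztp(p3), "collinear")
})

test_that("AND and XOR fits are independent", {
  anchors <- as.character(seq(0, 4990000, by = 10000))
  set.seed(9)
  p_and <- toy_pairs(200, class = "AND", seed = 1)
  p_xor <- toy_pairs(200, class = "XOR", seed = 2)
  res1 <- normalize_sample(rbind(p_and, p_xor))
  res2 <- normalize_sample(rbind(p_and, p_xor[sample(.N)]))
  b1 <- res1$fits[class == "AND", .(beta0, beta_fl, beta_gc, beta_ms, beta_ip)]
  b2 <- res2$fits[class == "AND", .(beta0, beta_fl, beta_gc, beta_ms, beta_ip)]
  expect_equal(b1, b2, tolerance = 1e-12)
})

test_that("normalize_sample fits two models per chromosome and combines output", {
  p <- rbind(toy_pairs(120, chrom = "chr1", class = "AND", seed = 3),
             toy_pairs(150, chrom = "chr1", class = "XOR", seed = 4),
             toy_pairs(120, chrom = "chr2", class = "AND", seed = 5),
             toy_pairs(150, chrom = "chr2", class = "XOR", seed = 6))
  res <- normalize_sample(p)
  expect_equal(nrow(res$fits), 4L)  # 2 classes x 2 chromosomes
  expect_setequal(res$fits$class, c("AND", "XOR"))
  expect_equal(nrow(res$normalized), nrow(p))
  expect_true(all(res$normalized$normalized > 0))
  expect_warning(
    normalize_sample(rbind(p, toy_pairs(20, chrom = "chr3", class = "AND"))),
    "skipping")
})
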