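test_that("condition anchor sets hit the target Jaccard overlap", {
  cfg <- sim_config(n_bins = 2000L, anchor_density = 0.05, seed = 13,
                    anchor_jaccard = 1.0)
  sets <- simulate_condition_anchors(cfg)
  expect_equal(sets[[1]], sets[[2]])
  for (target in c(0.54, 0.32)) {  # promoter-mark-like and divergent-mark-like
    cfg <- sim_config(n_bins = 2000L, anchor_density = 0.05, seed = 13,
                      anchor_jaccard = target)
    sets <- simulate_condition_anchors(cfg)
    expect_lt(abs(anchor_jaccard(sets[[1]], sets[[2]]) - target), 0.05)
  }
  expect_error(simulate_condition_anchors(
    sim_config(n_bins = 100L, anchor_density = 0.6, anchor_jaccard = 0.05)),
    "feasible")
})

test_that("emitted peaks re-bin to exactly the simulated anchors", {
  cfg <- small_sim_config(seed = 5)
  sets <- simulate_condition_anchors(cfg)
  peaks <- anchors_to_peaks(sets[[1]], cfg$resolution)
  rebinned <- peaks_to_anchors(peaks, cfg$resolution)
  expect_equal(rebinned, sets[[1]])
  # boundary-spanning peaks exist whenever adjacent anchors occur
  if (any(diff(sets[[1]]$chr1) == cfg$resolution))
    expect_true(any(peaks$end - peaks$start > cfg$resolution))
})

test_that("simulated samples carry all three pair classes and valid tables", {
  cfg <- small_sim_config(seed = 21)
  s <- simulate_sample(cfg, condition = 1, replicate = 1)
  expect_setequal(unique(s$pairs$class), c("AND", "XOR", "NOT"))
  with_cls <- s$pairs[s$pairs$class %in% c("AND", "XOR")]
  expect_true(all(with_cls$count >= 1))
  expect_true(all(with_cls$bin2 - with_cls$bin1 > 1000))
  expect_true(all(with_cls$bin1 %% cfg$resolution == 0))
  expect_true(all(is.finite(as.matrix(with_cls[, .(fl, gc, ms, ip)]))))
})

test_that("study generation is byte-identical under a fixed seed", {
  cfg <- small_sim_config(seed = 17)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_study(simulate_study(cfg), d1)
  write_study(simulate_study(cfg), d2)
  for (f in list.files(d1)) {
    expect_true(file.exists(file.path(d2, f)))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
})

test_that("noise-free replicates at high depth score near 1", {
  cfg <- sim_config(n_bins = 800L, n_chroms = 1L, depth = 4e6,
                    anchor_density = 0.08, noise_sd = 0, seed = 29)
  st <- simulate_study(cfg)
  res <- run_study(st, d = 3)
  reps <- res$scores["cond1_rep1", "cond1_rep2"]
  expect_gt(reps, 0.98)
})

test_that("the fitted regression recovers the generating coefficients", {
  cfg <- sim_config(n_bins = 2000L, n_chroms = 1L, depth = 2e5,
                    noise_sd = 0, decay_exponent = 0, loop_strength = 0,
                    seed = 41)
  s <- simulate_sample(cfg, 1, 1)
  xor <- s$pairs[s$pairs$class == "XOR"]
  fit <- fit_ztp(xor)
  # slopes recovered; the intercept absorbs the depth calibration
  expect_true(all(abs(fit$beta[-1] - cfg$beta_true[-1]) < 3 * fit$se[-1]))
})
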