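# Synthetic HP studies. The generative model mirrors what the pipeline
# assumes: per-bin features (fragment length, GC, mappability, short-range
# ChIP-efficiency counts), condition-specific anchor sets with a
# controlled Jaccard overlap, and Poisson counts with
#   log mu = beta . covariates + condition loop signal
#            - decay * log(distance) + replicate noise,
# kept conditional on being non-zero (i.e. zero-truncated, matching what
# a contact file records). Replicates of a condition share the anchor set
# and loop field and differ only in noise and count sampling.

#' Configuration for a synthetic HP study
#'
#' @param n_bins Bins per chromosome.
#' @param resolution Bin size in bp.
#' @param n_chroms Number of chromosomes (`"chr1"`, ...).
#' @param n_conditions,n_replicates Study layout; replicates of one
#'   condition are biological replicates.
#' @param anchor_density Fraction of bins that are ChIP-peak (anchor)
#'   bins in each condition.
#' @param anchor_jaccard Target Jaccard overlap between the anchor sets
#'   of two conditions (1 = identical peaks; promoter-mark studies sit
#'   near 0.5, more divergent marks near 0.3).
#' @param depth Expected total long-range contact count per sample.
#' @param decay_exponent Power-law slope of contact frequency against 1D
#'   distance.
#' @param beta_true 5-vector of regression coefficients (intercept, FL,
#'   GC, MS, IP) generating the bias structure.
#' @param noise_sd Standard deviation of replicate-specific log-normal
#'   noise on the contact rate.
#' @param loops_per_anchor Mean number of elevated "true loop" cells per
#'   anchor in each condition's latent signal field.
#' @param loop_strength Log-scale elevation of a loop cell.
#' @param binning_distance Maximum contact span generated, in bp.
#' @param seed Master seed; all randomness derives from it.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_bins = 2000L, resolution = 10000L, n_chroms = 2L,
                       n_conditions = 2L, n_replicates = 2L,
                       anchor_density = 0.05, anchor_jaccard = 0.54,
                       depth = 2e5, decay_exponent = 1,
                       beta_true = c(0.5, 0.3, -0.2, 0.1, 0.5),
                       noise_sd = 0.2, loops_per_anchor = 2,
                       loop_strength = 2, binning_distance = 1e6,
                       seed = 1L) {
  stopifnot(anchor_jaccard > 0, anchor_jaccard <= 1, depth > 0,
            length(beta_true) == 5L, all(is.finite(beta_true)),
            anchor_density > 0, anchor_density < 1, noise_sd >= 0)
  structure(as.list(environment()), class = "sim_config")
}

sim_chroms <- function(cfg) paste0("chr", seq_len(cfg$n_chroms))

#' Simulate per-condition anchor sets with a target Jaccard overlap
#'
#' Each condition gets `round(anchor_density * n_bins)` anchor bins per
#' chromosome; conditions share a core of bins sized so every pairwise
#' Jaccard index matches `anchor_jaccard` (within sampling error of the
#' rounding).
#'
#' @param cfg A `sim_config`.
#' @return A list of `anchor_set` objects, one per condition.
#' @export
simulate_condition_anchors <- function(cfg) {
  a <- round(cfg$anchor_density * cfg$n_bins)
  shared <- round(2 * a * cfg$anchor_jaccard / (1 + cfg$anchor_jaccard))
  private <- a - shared
  need <- shared + cfg$n_conditions * private
  if (shared > a || need > cfg$n_bins)
    stop("infeasible anchor_jaccard ", cfg$anchor_jaccard,
         " at density ", cfg$anchor_density, ": need ", need,
         " distinct bins per chromosome but have ", cfg$n_bins,
         "; feasible Jaccard range given the density is [",
         signif(max(0, 2 * a - cfg$n_bins) /
                  (2 * a - max(0, 2 * a - cfg$n_bins)), 3), ", 1]")
  set.seed(derive_seed(cfg$seed, "anchors"))
  sets <- replicate(cfg$n_conditions, list(), simplify = FALSE)
  for (ch in sim_chroms(cfg)) {
    pool <- sample.int(cfg$n_bins, need) - 1L
    core <- pool[seq_len(shared)]
    rest <- pool[-seq_len(shared)]
    for (cond in seq_len(cfg$n_conditions)) {
      priv <- if (private > 0)
        rest[((cond - 1) * private + 1):(cond * private)] else integer()
      sets[[cond]][[ch]] <- sort(c(core, priv)) * cfg$resolution
    }
  }
  lapply(sets, as_anchor_set)
}

#' Emit BED peaks realizing an anchor set
#'
#' Writes one ChIP peak per anchor bin, except that runs of adjacent
#' anchor bins are merged into a single boundary-spanning peak — so
#' re-binning the peaks with [peaks_to_anchors()] recovers exactly the
#' input anchor set while exercising the peak-spanning rule.
#'
#' @param anchors An `anchor_set`.
#' @param resolution Bin size in bp.
#' @return A `data.table` of `chrom, start, end` (0-based half-open).
#' @export
anchors_to_peaks <- function(anchors, resolution) {
  data.table::rbindlist(lapply(names(anchors), function(ch) {
    b <- anchors[[ch]]
    if (!length(b)) return(NULL)
    run_start <- b[c(TRUE, diff(b) != resolution)]
    run_end <- b[c(diff(b) != resolution, TRUE)]
    data.table::data.table(chrom = ch,
                           start = run_start + resolution %/% 4,
                           end = run_end + (3 * resolution) %/% 4)
  }))
}

simulate_bin_features <- function(cfg, anchors, sample_id) {
  set.seed(derive_seed(cfg$seed, "features", sample_id))
  data.table::rbindlist(lapply(sim_chroms(cfg), function(ch) {
    starts <- (seq_len(cfg$n_bins) - 1L) * cfg$resolution
    is_anchor <- starts %in% anchors[[ch]]
    data.table::data.table(
      chrom = ch,
      bin_start = starts,
      effective_length = cfg$resolution * runif(cfg$n_bins, 0.5, 1),
      gc = runif(cfg$n_bins, 0.3, 0.7),
      mappability = runif(cfg$n_bins, 0.7, 1),
      # ChIP pulls short-range reads toward peaks: enriched at anchors
      short_count = rgamma(cfg$n_bins, shape = 2, scale = 50) *
        ifelse(is_anchor, 5, 1) + 1)
  }))
}

# Condition-level latent signal: sparse elevated "loop" cells among the
# candidate (anchor, partner) pairs, fixed per condition.
simulate_loop_field <- function(cfg, condition, candidates) {
  set.seed(derive_seed(cfg$seed, "signal", condition))
  n_loops <- min(nrow(candidates),
                 round(cfg$loops_per_anchor * cfg$anchor_density *
                         cfg$n_bins * cfg$n_chroms))
  idx <- sample.int(nrow(candidates), n_loops)
  signal <- numeric(nrow(candidates))
  signal[idx] <- cfg$loop_strength
  signal
}

candidate_pairs <- function(cfg, anchors) {
  m2 <- cfg$binning_distance %/% cfg$resolution
  chrom_len <- cfg$n_bins * cfg$resolution
  data.table::rbindlist(lapply(names(anchors), function(ch) {
    a <- anchors[[ch]]
    if (!length(a)) return(NULL)
    dt <- data.table::CJ(anchor = a, k = seq_len(m2))
    dt <- data.table::rbindlist(list(
      dt[, .(chrom = ch, bin1 = anchor, bin2 = anchor + k * cfg$resolution)],
      dt[, .(chrom = ch, bin1 = anchor - k * cfg$resolution, bin2 = anchor)]))
    dt <- dt[bin1 >= 0 & bin2 < chrom_len]
    unique(dt[bin1 < bin2])
  }))
}

#' Simulate one HP sample
#'
#' Generates the long-range AND/XOR contact tables of one replicate of
#' one condition: candidate anchor-to-bin pairs within the binning
#' distance receive Poisson counts with the log-linear bias model plus
#' the condition's loop field, distance decay and replicate noise;
#' zero-count pairs are dropped (contact files only record observed
#' contacts). A handful of non-anchor background pairs are added and
#' classified NOT, so the classifier's discard path is exercised.
#'
#' @param cfg A `sim_config`.
#' @param condition Condition index (1-based).
#' @param replicate Replicate index within the condition.
#' @param anchors Per-condition anchor sets from
#'   [simulate_condition_anchors()].
#' @param features Optional pre-built per-bin feature table (defaults to
#'   a fresh one for this sample).
#' @return A list: `pairs` (classified bin-pair table with AND/XOR/NOT),
#'   `features`, `anchors` (this condition's set), `sample_id`.
#' @export
simulate_sample <- function(cfg, condition, replicate, anchors = NULL,
                            features = NULL) {
  if (is.null(anchors)) anchors <- simulate_condition_anchors(cfg)
  cond_anchors <- anchors[[condition]]
  sample_id <- paste0("cond", condition, "_rep", replicate)
  if (is.null(features))
    features <- simulate_bin_features(cfg, cond_anchors, sample_id)

  cand <- candidate_pairs(cfg, cond_anchors)
  signal <- simulate_loop_field(cfg, condition, cand)
  cand <- join_features(cand, features)

  set.seed(derive_seed(cfg$seed, "counts", condition, replicate))
  X <- cbind(1, cand$fl, cand$gc, cand$ms, cand$ip)
  dist_bins <- (cand$bin2 - cand$bin1) / cfg$resolution
  log_mu <- as.vector(X %*% cfg$beta_true) + signal -
    cfg$decay_exponent * log(dist_bins) +
    rnorm(nrow(cand), sd = cfg$noise_sd)
  mu <- exp(log_mu - max(log_mu))          # overflow-safe before scaling
  mu <- mu * (cfg$depth / sum(mu))
  cand[, count := rpois(.N, mu)]
  cand <- cand[count > 0]

  # background pairs away from anchors -> exercises the NOT class
  bg_n <- 50L
  bg <- data.table::rbindlist(lapply(sim_chroms(cfg), function(ch) {
    non_anchor <- setdiff((seq_len(cfg$n_bins) - 1L) * cfg$resolution,
                          cond_anchors[[ch]])
    b1 <- sample(head(non_anchor, -5), bg_n)
    off <- sample.int(cfg$binning_distance %/% cfg$resolution, bg_n)
    data.table::data.table(chrom = ch, bin1 = b1,
                           bin2 = b1 + off * cfg$resolution)
  }))
  bg <- bg[bin2 < cfg$n_bins * cfg$resolution]
  bg <- bg[!paste0(chrom, ":", bin2) %in%
             unlist(lapply(names(cond_anchors), function(ch)
               paste0(ch, ":", cond_anchors[[ch]])))]
  bg <- join_features(bg, features)
  bg[, count := 1L + rpois(.N, 1)]

  all_pairs <- data.table::rbindlist(list(cand, bg), use.names = TRUE)
  cls <- classify_pairs(all_pairs, cond_anchors)
  pairs <- data.table::rbindlist(cls)
  data.table::setorder(pairs, chrom, bin1, bin2)
  list(pairs = pairs[], features = features, anchors = cond_anchors,
       sample_id = sample_id)
}

#' Simulate a complete multi-sample HP study
#'
#' @param cfg A `sim_config`.
#' @return A list: `samples` (named list of classified bin-pair tables),
#'   `features` (named list), `labels` (condition label per sample),
#'   `anchors` (per-condition `anchor_set`s), `union_anchors`, `config`.
#' @export
simulate_study <- function(cfg) {
  anchors <- simulate_condition_anchors(cfg)
  samples <- list(); features <- list(); labels <- character()
  for (cond in seq_len(cfg$n_conditions)) {
    for (rep in seq_len(cfg$n_replicates)) {
      s <- simulate_sample(cfg, cond, rep, anchors = anchors)
      samples[[s$sample_id]] <- s$pairs
      features[[s$sample_id]] <- s$features
      labels[s$sample_id] <- paste0("cond", cond)
    }
  }
  list(samples = samples, features = features, labels = labels,
       anchors = anchors, union_anchors = union_anchors(anchors),
       config = cfg)
}

#' Write a simulated study to disk in the pipeline's file dialect
#'
#' Emits, per sample: `<id>.<chrom>.AND.txt` / `.XOR.txt` bin-pair
#' tables, `<id>.features.txt`, and `<id>.peaks.bed`; plus a
#' `study.yaml` naming the samples.
#'
#' @param study Result of [simulate_study()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- study$config
  for (id in names(study$samples)) {
    p <- study$samples[[id]]
    for (ch in unique(p$chrom)) for (cl in c("AND", "XOR")) {
      sub <- p[p$chrom == ch & p$class == cl]
      write_bin_pairs(sub, file.path(dir, paste0(id, ".", ch, ".", cl, ".txt")))
    }
    f <- data.table::copy(study$features[[id]])
    data.table::setnames(f, "chrom", "chr")
    data.table::fwrite(f, file.path(dir, paste0(id, ".features.txt")), sep = "\t")
    cond <- match(study$labels[[id]], paste0("cond", seq_len(cfg$n_conditions)))
    peaks <- anchors_to_peaks(study$anchors[[cond]], cfg$resolution)
    data.table::fwrite(peaks, file.path(dir, paste0(id, ".peaks.bed")),
                       sep = "\t", col.names = FALSE)
  }
  yaml::write_yaml(list(
    resolution = cfg$resolution, binning_distance = cfg$binning_distance,
    chromosomes = sim_chroms(cfg), samples = as.list(names(study$samples)),
    smoothing_d = "tune", seed = cfg$seed), file.path(dir, "study.yaml"))
  invisible(dir)
}

#' Simulate bin pairs straight from the zero-truncated Poisson model
#'
#' Covariates are independent standard normals and counts are exact ZTP
#' draws at `mu = exp(beta . x)` — the clean parameter-recovery setting
#' for [fit_ztp()], with no loop signal, decay or extra noise.
#'
#' @param n Number of bin pairs.
#' @param beta True coefficient 5-vector.
#' @param seed Integer seed.
#' @return A bin-pair `data.table` with covariates and ZTP counts.
#' @export
simulate_ztp_pairs <- function(n, beta, seed = 1L) {
  stopifnot(length(beta) == 5L)
  set.seed(seed)
  dt <- data.table::data.table(
    chrom = "chr1",
    bin1 = (seq_len(n) - 1L) * 2e4,
    bin2 = (seq_len(n) - 1L) * 2e4 + 1e4,
    fl = rnorm(n), gc = rnorm(n), ms = rnorm(n), ip = rnorm(n))
  mu <- exp(as.vector(cbind(1, dt$fl, dt$gc, dt$ms, dt$ip) %*% beta))
  dt[, count := rztp(.N, mu)]
  dt[, class := "XOR"]
  dt[]
}
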