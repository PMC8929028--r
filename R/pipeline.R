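# Workflow glue: normalize every sample of a study, build per-chromosome
# anchor-by-offset matrices on the shared union anchor set, and score all
# sample pairs. Works on in-memory studies (as from simulate_study()) or
# on a directory in the file dialect written by write_study().

#' Normalize every sample of a study
#'
#' Runs [normalize_sample()] (2 ZTP fits per chromosome: AND and XOR)
#' on each sample's classified pairs; NOT pairs are discarded here.
#'
#' @param samples Named list of classified bin-pair tables.
#' @param fitted_type Passed to [predict_fitted()].
#' @return A list: `normalized` (named list of tables) and `fits` (one
#'   `data.table` of model summaries with a `sample` column, the
#'   AIC/BIC-per-fit summary file's content).
#' @export
normalize_study <- function(samples, fitted_type = "truncated") {
  normalized <- list(); fits <- list()
  for (id in names(samples)) {
    p <- data.table::as.data.table(samples[[id]])
    res <- normalize_sample(p[class %in% c("AND", "XOR")],
                            fitted_type = fitted_type)
    normalized[[id]] <- res$normalized
    fits[[id]] <- data.table::copy(res$fits)[, sample := id]
  }
  list(normalized = normalized, fits = data.table::rbindlist(fits))
}

#' Build per-chromosome matrices for every sample
#'
#' @param normalized Named list of normalized pair tables.
#' @param union_anchors Study-wide union `anchor_set`.
#' @param config A `study_config` (or `sim_config`; only `resolution`,
#'   `binning_distance` and `m` are consulted).
#' @return Named list (sample) of named lists (chromosome) of
#'   `anchor_offset_matrix`.
#' @export
study_matrices <- function(normalized, union_anchors, config) {
  if (is.null(config$m))
    config$m <- as.integer(2 * config$binning_distance / config$resolution)
  chroms <- names(union_anchors)
  lapply(normalized, function(p)
    setNames(lapply(chroms, function(ch)
      build_matrix(p[p$chrom == ch], union_anchors, config, chrom = ch)),
      chroms))
}

#' Score all sample pairs of a study, tuning the smoothing if asked
#'
#' End-to-end comparison stage: optionally tunes the smoothing window on
#' the most dissimilar-looking sample pair (the pair with the lowest
#' unsmoothed score), then scores every pair at the chosen window.
#'
#' @param mats Output of [study_matrices()].
#' @param d Integer smoothing window, or `"tune"`.
#' @param seed Seed for tuning subsamples.
#' @return A list: `scores`, `per_chrom`, `sd` (see [score_all_pairs()]),
#'   plus `d` and, when tuned, `tuning` (the trajectory).
#' @export
study_scores <- function(mats, d = 0L, seed = 1L) {
  tuning <- NULL
  if (identical(d, "tune")) {
    ids <- names(mats)
    raw <- score_all_pairs(mats, 0L)$scores
    off <- which(raw == min(raw[upper.tri(raw)]), arr.ind = TRUE)[1, ]
    tuned <- tune_smoothing(mats[[off[1]]], mats[[off[2]]], seed = seed)
    d <- tuned$d
    tuning <- tuned$trajectory
  }
  out <- score_all_pairs(mats, d)
  out$d <- d
  out$tuning <- tuning
  out
}

#' Run the full pipeline on an in-memory study
#'
#' [normalize_study()] -> [study_matrices()] -> [study_scores()].
#'
#' @param study A study as from [simulate_study()] (elements `samples`,
#'   `union_anchors`, `config`).
#' @param d Smoothing window or `"tune"`.
#' @param seed Seed for tuning.
#' @return As [study_scores()], plus `fits`, `matrices` and `d`.
#' @export
run_study <- function(study, d = 0L, seed = 1L) {
  norm <- normalize_study(study$samples)
  mats <- study_matrices(norm$normalized, study$union_anchors, study$config)
  res <- study_scores(mats, d = d, seed = seed)
  res$fits <- norm$fits
  res$matrices <- mats
  res
}

#' Normalize a study directory on disk
#'
#' Reads `<id>.<chrom>.{AND,XOR}.txt` tables for every sample and
#' chromosome named in the YAML config, fits the 2-per-chromosome ZTP
#' models, and writes per-sample combined normalized tables
#' (`<id>.normalized.txt`), the model-summary file
#' (`model_summary.txt`), the binned anchor list (`anchors.txt`, union
#' of all samples' peak files), and a JSON run manifest.
#'
#' @param dir Study directory (as written by [write_study()]).
#' @param config_path YAML config path (default `dir/study.yaml`).
#' @return Invisibly, the list from [normalize_study()] plus the union
#'   `anchor_set`.
#' @export
hp_normalize_dir <- function(dir, config_path = file.path(dir, "study.yaml")) {
  cfg <- read_study_config(config_path)
  ids <- unlist(cfg$samples)
  anchor_sets <- lapply(ids, function(id)
    read_peaks_to_anchors(file.path(dir, paste0(id, ".peaks.bed")), cfg$resolution))
  uni <- union_anchors(anchor_sets)
  write_anchor_set(uni, file.path(dir, "anchors.txt"))
  samples <- setNames(lapply(ids, function(id) {
    data.table::rbindlist(unlist(lapply(cfg$chromosomes, function(ch)
      lapply(c("AND", "XOR"), function(cl) {
        f <- file.path(dir, paste0(id, ".", ch, ".", cl, ".txt"))
        if (!file.exists(f)) stop("missing input file: ", f)
        read_bin_pairs(f, cl, cfg$resolution)
      })), recursive = FALSE))
  }), ids)
  res <- normalize_study(samples)
  for (id in ids)
    data.table::fwrite(res$normalized[[id]],
                       file.path(dir, paste0(id, ".normalized.txt")), sep = "\t")
  data.table::fwrite(res$fits, file.path(dir, "model_summary.txt"), sep = "\t")
  write_manifest(dir, "normalize", cfg,
                 outputs = c(paste0(ids, ".normalized.txt"),
                             "model_summary.txt", "anchors.txt"))
  res$union_anchors <- uni
  invisible(res)
}

#' Compare all samples of a normalized study directory
#'
#' Reads the normalized tables and anchor list written by
#' [hp_normalize_dir()], scores all pairs (optionally restricted to one
#' chromosome), and writes `scores.txt` (matrix), `scores_per_chrom.txt`
#' and, when tuned, `tuning.txt`.
#'
#' @param dir Study directory.
#' @param config_path YAML config path.
#' @param chrom Optional single chromosome to restrict to.
#' @return Invisibly, the [study_scores()] result.
#' @export
hp_compare_dir <- function(dir, config_path = file.path(dir, "study.yaml"),
                           chrom = NULL) {
  cfg <- read_study_config(config_path)
  ids <- unlist(cfg$samples)
  uni <- read_anchor_set(file.path(dir, "anchors.txt"))
  if (!is.null(chrom)) uni <- as_anchor_set(uni[chrom])
  normalized <- setNames(lapply(ids, function(id) {
    dt <- data.table::fread(file.path(dir, paste0(id, ".normalized.txt")))
    if (!is.null(chrom)) dt <- dt[dt$chrom %in% chrom]
    dt
  }), ids)
  mats <- study_matrices(normalized, uni, cfg)
  res <- study_scores(mats, d = cfg$smoothing_d, seed = cfg$seed)
  write_score_matrix(res$scores, file.path(dir, "scores.txt"))
  if (!is.null(res$per_chrom))
    data.table::fwrite(res$per_chrom, file.path(dir, "scores_per_chrom.txt"),
                       sep = "\t")
  if (!is.null(res$tuning))
    data.table::fwrite(res$tuning, file.path(dir, "tuning.txt"), sep = "\t")
  write_manifest(dir, "compare", cfg,
                 outputs = c("scores.txt", "scores_per_chrom.txt"))
  invisible(res)
}

write_manifest <- function(dir, step, cfg, outputs) {
  files <- file.path(dir, outputs)
  files <- files[file.exists(files)]
  manifest <- list(
    step = step,
    version = as.character(utils::packageVersion("hprep")),
    timestamp = format(Sys.time(), tz = "UTC"),
    seed = cfg$seed,
    config = cfg[c("resolution", "binning_distance", "chromosomes",
                   "smoothing_d")],
    outputs = lapply(setNames(files, basename(files)), function(f)
      unname(tools::md5sum(f))))
  jsonlite::write_json(manifest, file.path(dir, paste0("manifest_", step, ".json")),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
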