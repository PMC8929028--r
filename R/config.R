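#' Study configuration
#'
#' Bundles the binning geometry and sample bookkeeping shared by the whole
#' pipeline. The matrix width is `m = 2 * binning_distance / resolution`
#' columns (signed offsets -m/2..-1, 1..m/2; there is no offset-0 column).
#'
#' @param resolution Bin size in bp (e.g. 5000 or 10000).
#' @param binning_distance Maximum anchor-to-bin span retained, in bp.
#'   1 Mb is the recommended default; interactions beyond it are sparse
#'   and highly variable.
#' @param chromosomes Character vector of chromosome names, in order.
#' @param samples Named list or character vector of sample identifiers
#'   (optionally mapping to file paths).
#' @param smoothing_d Non-negative integer smoothing window half-width,
#'   or the string `"tune"` to request data-driven tuning.
#' @param seed Non-negative integer master seed.
#'
#' @return An object of class `study_config`.
#' @examples
#' cfg <- study_config(resolution = 10000, chromosomes = "chr1",
#'                     samples = c("s1", "s2"))
#' cfg$m  # 200 columns at 10 Kb resolution and 1 Mb binning distance
#' @export
study_config <- function(resolution,
                         binning_distance = 1e6,
                         chromosomes = character(),
                         samples = character(),
                         smoothing_d = "tune",
                         seed = 1L) {
  if (!is.numeric(resolution) || length(resolution) != 1L || resolution <= 0)
    stop("`resolution` must be a single positive number of bp")
  if (!is.numeric(binning_distance) || binning_distance <= 0 ||
      binning_distance %% resolution != 0)
    stop("`binning_distance` must be a positive integer multiple of `resolution`")
  ids <- if (is.list(samples)) names(samples) else as.character(samples)
  if (anyDuplicated(ids)) stop("sample identifiers must be unique")
  if (!identical(smoothing_d, "tune")) {
    if (!is.numeric(smoothing_d) || length(smoothing_d) != 1L ||
        smoothing_d < 0 || smoothing_d %% 1 != 0)
      stop("`smoothing_d` must be a non-negative integer or \"tune\"")
    smoothing_d <- as.integer(smoothing_d)
  }
  if (!is.numeric(seed) || seed < 0) stop("`seed` must be a non-negative integer")
  structure(list(
    resolution = as.integer(resolution),
    binning_distance = as.integer(binning_distance),
    chromosomes = as.character(chromosomes),
    samples = samples,
    smoothing_d = smoothing_d,
    seed = as.integer(seed),
    m = as.integer(2 * binning_distance / resolution)
  ), class = "study_config")
}

#' Read a study configuration from YAML
#'
#' @param path Path to a YAML file with fields matching the arguments of
#'   [study_config()].
#' @return A `study_config`.
#' @export
read_study_config <- function(path) {
  y <- yaml::read_yaml(path)
  study_config(
    resolution = y$resolution,
    binning_distance = y$binning_distance %||% 1e6,
    chromosomes = y$chromosomes %||% character(),
    samples = y$samples %||% character(),
    smoothing_d = y$smoothing_d %||% "tune",
    seed = y$seed %||% 1L
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.study_config <- function(x, ...) {
  cat("HP study configuration\n")
  cat("  resolution:      ", x$resolution, "bp\n")
  cat("  binning distance:", x$binning_distance, "bp (m =", x$m, "columns)\n")
  cat("  chromosomes:     ", length(x$chromosomes), "\n")
  n_s <- if (is.list(x$samples)) length(x$samples) else length(x$samples)
  cat("  samples:         ", n_s, "\n")
  cat("  smoothing d:     ", format(x$smoothing_d), "\n")
  invisible(x)
}
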