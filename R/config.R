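#' Default pipeline configuration
#'
#' Returns the run configuration controlling assembly, bait mapping, quality
#' trimming and picking.  All values can be overridden by arguments, or loaded
#' from a YAML file with [load_config()].
#'
#' @param ... named overrides of default keys.
#' @return a validated named list of class `run_config`.
#' @details Keys and defaults:
#' \describe{
#'   \item{k_assembly (31)}{odd k-mer size for de Bruijn assembly.}
#'   \item{k_bait (21)}{odd k-mer size for bait-read mapping.}
#'   \item{min_kmer_count (2)}{minimum k-mer multiplicity kept in the graph.}
#'   \item{auto_min_count (TRUE)}{raise the multiplicity cutoff to the valley
#'     of the k-mer histogram at high depth (see [assemble()]).}
#'   \item{tip_max_len (62)}{maximum tip length clipped, bp (2 x k_assembly).}
#'   \item{min_frac_ds (0.5)}{minimum matched k-mer fraction to place a
#'     direct-shotgun read.}
#'   \item{min_frac_bait (0.3)}{minimum matched k-mer fraction for chimera-rich
#'     WGA bait reads, which may legitimately match over only part of their
#'     length.}
#'   \item{min_bait_reads (1)}{bait reads required to mark a contig as target.}
#'   \item{genome_size_estimate (1e5)}{yardstick genome size, bp, for coverage
#'     subsampling.}
#'   \item{target_cov (100)}{coverage target for the short-read subsample.}
#'   \item{trim_q (20)}{quality threshold for sliding-window trimming.}
#'   \item{trim_window_frac (0.1)}{window size as a fraction of read length.}
#'   \item{trim_min_length (20)}{minimum kept read length after trimming.}
#'   \item{trim_platform_a (FALSE)}{whether long single-end reads are trimmed.}
#'   \item{seed (1)}{random seed for stochastic steps.}
#' }
#' @export
run_config <- function(...) {
  cfg <- list(
    k_assembly = 31L,
    k_bait = 21L,
    min_kmer_count = 2L,
    auto_min_count = TRUE,
    tip_max_len = 62L,
    min_frac_ds = 0.5,
    min_frac_bait = 0.3,
    min_bait_reads = 1L,
    genome_size_estimate = 1e5,
    target_cov = 100,
    trim_q = 20,
    trim_window_frac = 0.1,
    trim_min_length = 20L,
    trim_platform_a = FALSE,
    seed = 1L
  )
  over <- list(...)
  if (length(over)) {
    unknown <- setdiff(names(over), names(cfg))
    if (length(unknown)) stop("unknown config keys: ",
                              paste(unknown, collapse = ", "))
    cfg[names(over)] <- over
  }
  validate_config(cfg)
}

#' Load a pipeline configuration from a YAML file
#'
#' @param path YAML file; keys match [run_config()].
#' @param ... overrides applied after loading (CLI flags beat file keys).
#' @return a validated `run_config`.
#' @export
load_config <- function(path, ...) {
  vals <- yaml::read_yaml(path)
  do.call(run_config, utils::modifyList(vals, list(...)))
}

validate_config <- function(cfg) {
  need_int <- c("k_assembly", "k_bait", "min_kmer_count", "tip_max_len",
                "min_bait_reads", "trim_min_length", "seed")
  for (k in need_int) cfg[[k]] <- as.integer(cfg[[k]])
  stopifnot(
    cfg$k_assembly %% 2L == 1L, cfg$k_assembly >= 15L, cfg$k_assembly <= 31L,
    cfg$k_bait %% 2L == 1L, cfg$k_bait >= 15L, cfg$k_bait <= 31L,
    cfg$min_kmer_count >= 1L,
    cfg$tip_max_len >= 0L,
    cfg$min_frac_ds > 0, cfg$min_frac_ds <= 1,
    cfg$min_frac_bait > 0, cfg$min_frac_bait <= 1,
    cfg$min_bait_reads >= 0L,
    cfg$genome_size_estimate > 0,
    cfg$target_cov > 0,
    cfg$trim_q >= 0,
    cfg$trim_window_frac > 0, cfg$trim_window_frac <= 1,
    cfg$trim_min_length >= 1L
  )
  structure(cfg, class = c("run_config", "list"))
}
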