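#' Select bait-supported contigs
#'
#' Returns contigs that attracted at least `min_bait_reads` assigned WGA
#' bait reads — the contigs considered to originate from the target
#' organism.
#'
#' @param assembly an `Assembly`.
#' @param bait_assignments placement data frame from [assign_read()] of bait
#'   reads against the assembly's contigs.
#' @param min_bait_reads inclusive threshold (default 1).
#' @return character vector of selected contig ids.
#' @export
pick_bait_contigs <- function(assembly, bait_assignments, min_bait_reads = 1) {
  if (nrow(bait_assignments) == 0L) return(character(0))
  stopifnot(all(bait_assignments$contig_id %in% assembly$contigs$id))
  tab <- table(bait_assignments$contig_id)
  names(tab)[tab >= min_bait_reads]
}

pair_base <- function(ids) sub("/[12]$", "", ids)
is_mate <- function(ids) grepl("/[12]$", ids)

#' Recover reads placed on selected contigs
#'
#' Returns the reads of `read_universe` whose best placement lies on a
#' selected contig.  For paired reads (ids ending `/1`, `/2`), if either
#' mate qualifies both are picked, provided the mate is itself in the
#' universe; a read whose mate is absent (lost in QC) is picked as a single.
#'
#' @param assembly an `Assembly` with placements.
#' @param selected_contigs contig ids, a subset of the assembly's contigs.
#' @param read_universe character vector of candidate read ids.
#' @return character vector of picked read ids (subset of `read_universe`).
#' @export
recover_reads <- function(assembly, selected_contigs, read_universe) {
  stopifnot(all(selected_contigs %in% assembly$contigs$id))
  if (length(selected_contigs) == 0L) return(character(0))
  pl <- assembly$placements
  hit <- pl$read_id[pl$contig_id %in% selected_contigs]
  picked <- intersect(read_universe, hit)
  # pair completion: either mate qualifying pulls in the other
  mates <- picked[is_mate(picked)]
  if (length(mates)) {
    base <- unique(pair_base(mates))
    both <- c(paste0(base, "/1"), paste0(base, "/2"))
    picked <- union(picked, intersect(both, read_universe))
  }
  picked
}

#' Subsample reads to a target coverage
#'
#' Uniform random subsample of reads (pairs kept or dropped atomically) so
#' that total bases approximately equal `target_cov * genome_size_estimate`.
#' If the available bases do not exceed the target, the input is returned
#' unchanged.
#'
#' @param reads read data frame; mates identified by ids ending `/1`, `/2`.
#' @param genome_size_estimate yardstick genome size, bp.
#' @param target_cov target coverage.
#' @param seed random seed.
#' @return the subsampled read data frame (pairs stay adjacent).
#' @export
subsample_to_coverage <- function(reads, genome_size_estimate, target_cov,
                                  seed = NULL) {
  stopifnot(genome_size_estimate > 0, target_cov > 0)
  target <- target_cov * genome_size_estimate
  if (nrow(reads) == 0L || sum(nchar(reads$sequence)) <= target) return(reads)
  grp <- ifelse(is_mate(reads$id), pair_base(reads$id), reads$id)
  with_seed(seed, {
    units <- unique(grp)
    perm <- sample(units)
    bases <- vapply(split(nchar(reads$sequence), grp)[perm], sum, numeric(1))
    keep_units <- perm[cumsum(bases) <= target]
    out <- reads[grp %in% keep_units, , drop = FALSE]
    rownames(out) <- NULL
    out
  })
}

#' Run the differential reads picking pipeline
#'
#' Executes the six-step bait-guided picking pipeline:
#' \enumerate{
#'   \item assemble the long single-end direct-shotgun (platform A) reads;
#'   \item map the WGA bait reads to the resulting contigs;
#'   \item recover the platform-A reads placed on bait-supported contigs;
#'   \item co-assemble the recovered A reads with the quality-trimmed,
#'     coverage-subsampled platform-B pairs (plus QC singletons);
#'   \item pick the platform-B reads co-assembled with picked A reads, i.e.
#'     placed on co-assembly contigs that carry at least one picked A read;
#'   \item re-assemble all picked reads into the final assembly.
#' }
#' Per-step read and base counts are logged to stderr and returned.
#'
#' @param bait_reads WGA bait read data frame.
#' @param platform_a_reads long single-end direct-shotgun read data frame.
#' @param platform_b_pairs list with `r1` and `r2` read data frames aligned
#'   by pair (e.g. from [split_pairs()]).
#' @param config a [run_config()].
#' @return a `PickResult`: list with `step3_picked_ids`,
#'   `step5_picked_pair_ids`, `step5_picked_single_ids`, `counts` (per-step
#'   read/base accounting), `final_assembly`, and the pickable universes
#'   (`universe_a_ids`, `universe_b_ids`) used by [evaluate_picking()].
#' @export
run_pipeline <- function(bait_reads, platform_a_reads, platform_b_pairs,
                         config = run_config()) {
  stopifnot(nrow(bait_reads) > 0, nrow(platform_a_reads) > 0,
            nrow(platform_b_pairs$r1) > 0)
  config <- validate_config(config)
  counts <- list()
  note <- function(step, label, df) {
    counts[[step]] <<- list(label = label, n_reads = nrow(df),
                            n_bases = sum(nchar(df$sequence)))
    log_step(step, label, nrow(df), sum(nchar(df$sequence)))
  }
  note("input_bait", "WGA bait reads", bait_reads)
  note("input_a", "platform A DS reads", platform_a_reads)
  note("input_b", "platform B DS reads",
       rbind(platform_b_pairs$r1, platform_b_pairs$r2))

  # step 1: assemble platform A reads
  asm1 <- assemble(platform_a_reads, k = config$k_assembly,
                   min_kmer_count = config$min_kmer_count,
                   tip_max_len = config$tip_max_len,
                   min_frac = config$min_frac_ds,
                   auto_min_count = config$auto_min_count)
  if (nrow(asm1$contigs) == 0L) {
    stop("step 1 (platform A assembly) produced no contigs")
  }
  message(sprintf("[step1] assembled %d contigs (%s bp)",
                  nrow(asm1$contigs),
                  format(sum(nchar(asm1$contigs$sequence)), big.mark = ",")))

  # step 2: map bait reads to the step-1 contigs
  bait_idx <- build_index(asm1$contigs, k = config$k_bait)
  bait_pl <- assign_read(bait_reads, bait_idx,
                         min_frac = config$min_frac_bait)
  if (nrow(bait_pl) == 0L) stop("step 2 (bait mapping) assigned no reads")
  message(sprintf("[step2] %d/%d bait reads mapped", nrow(bait_pl),
                  nrow(bait_reads)))

  # step 3: recover platform-A reads on bait-supported contigs
  sel1 <- pick_bait_contigs(asm1, bait_pl, config$min_bait_reads)
  picked_a <- recover_reads(asm1, sel1, platform_a_reads$id)
  if (length(picked_a) == 0L) {
    stop("step 3 (platform A recovery) picked no reads")
  }
  a_picked <- platform_a_reads[platform_a_reads$id %in% picked_a, ,
                               drop = FALSE]
  note("step3", "picked platform A reads", a_picked)

  # step 4: trim, subsample, co-assemble
  tr <- trim_pairs(platform_b_pairs$r1, platform_b_pairs$r2,
                   q_threshold = config$trim_q,
                   window_frac = config$trim_window_frac,
                   min_length = config$trim_min_length)
  interleaved <- rbind(tr$kept_r1, tr$kept_r2)
  ord <- order(match(pair_base(interleaved$id), pair_base(tr$kept_r1$id)),
               interleaved$id)
  interleaved <- interleaved[ord, , drop = FALSE]
  b_sub <- subsample_to_coverage(interleaved, config$genome_size_estimate,
                                 config$target_cov, seed = config$seed)
  note("step4_b_pool", "trimmed+subsampled platform B reads",
       rbind(b_sub, tr$kept_singles))
  co_reads <- rbind(a_picked, b_sub, tr$kept_singles)
  asm2 <- assemble(co_reads, k = config$k_assembly,
                   min_kmer_count = config$min_kmer_count,
                   tip_max_len = config$tip_max_len,
                   min_frac = config$min_frac_ds,
                   auto_min_count = config$auto_min_count)
  if (nrow(asm2$contigs) == 0L) {
    stop("step 4 (co-assembly) produced no contigs")
  }
  message(sprintf("[step4] co-assembly: %d contigs (%s bp)",
                  nrow(asm2$contigs),
                  format(sum(nchar(asm2$contigs$sequence)), big.mark = ",")))

  # step 5: pick platform-B reads co-assembled with picked A reads
  pl2 <- asm2$placements
  sel2 <- unique(pl2$contig_id[pl2$read_id %in% picked_a])
  b_universe <- c(b_sub$id, tr$kept_singles$id)
  picked_b <- recover_reads(asm2, sel2, b_universe)
  if (length(picked_b) == 0L) {
    stop("step 5 (platform B recovery) picked no reads")
  }
  picked_b_pairs <- unique(pair_base(picked_b[is_mate(picked_b)]))
  picked_b_singles <- picked_b[!is_mate(picked_b)]
  b_picked <- rbind(b_sub[b_sub$id %in% picked_b, , drop = FALSE],
                    tr$kept_singles[tr$kept_singles$id %in% picked_b, ,
                                    drop = FALSE])
  note("step5", "picked platform B reads", b_picked)

  # step 6: re-assemble all picked reads
  final_reads <- rbind(a_picked, b_picked)
  asm3 <- assemble(final_reads, k = config$k_assembly,
                   min_kmer_count = config$min_kmer_count,
                   tip_max_len = config$tip_max_len,
                   min_frac = config$min_frac_ds,
                   auto_min_count = config$auto_min_count)
  if (nrow(asm3$contigs) == 0L) {
    stop("step 6 (re-assembly) produced no contigs")
  }
  message(sprintf("[step6] final assembly: %d contigs (%s bp)",
                  nrow(asm3$contigs),
                  format(sum(nchar(asm3$contigs$sequence)), big.mark = ",")))

  structure(list(
    step3_picked_ids = picked_a,
    step5_picked_pair_ids = picked_b_pairs,
    step5_picked_single_ids = picked_b_singles,
    counts = counts,
    final_assembly = asm3,
    universe_a_ids = platform_a_reads$id,
    universe_b_ids = b_universe
  ), class = "PickResult")
}

#' @export
print.PickResult <- function(x, ...) {
  cat("PickResult:", length(x$step3_picked_ids), "platform-A reads,",
      length(x$step5_picked_pair_ids), "platform-B pairs,",
      length(x$step5_picked_single_ids), "platform-B singles picked;",
      nrow(x$final_assembly$contigs), "final contigs\n")
  invisible(x)
}

#' All individual read ids picked by a pipeline run
#'
#' @param result a `PickResult`.
#' @return character vector of read ids (platform A reads, both mates of
#'   picked pairs, picked singles).
#' @export
picked_read_ids <- function(result) {
  pp <- result$step5_picked_pair_ids
  mates <- if (length(pp)) c(paste0(pp, "/1"), paste0(pp, "/2"))
           else character(0)
  c(result$step3_picked_ids, mates, result$step5_picked_single_ids)
}

#' Evaluate a picking run against simulation truth
#'
#' Computes picking precision (target-labelled picked reads over all picked
#' reads; `NA` when nothing was picked) and recall (target-labelled picked
#' reads over target-labelled reads eligible for picking, i.e. all platform-A
#' input reads plus the platform-B reads that survived trimming and
#' subsampling).  When genome sequences are supplied, also measures final
#' assembly quality by exact canonical k-mer comparison: target completeness
#' (fraction of target-genome k-mers present in the final contigs) and the
#' contaminant k-mer fraction (fraction of final-contig k-mers found only in
#' the contaminant genome).
#'
#' @param result a `PickResult` from [run_pipeline()].
#' @param truth truth sidecar data frame covering every input read.
#' @param target_id genome id of the target organism in the truth table.
#' @param target_genome,contaminant_genome `SynGenome` or DNA strings;
#'   optional.
#' @param k k-mer size for the assembly comparison (default 31).
#' @return a `PickEval`: list with `precision`, `recall`,
#'   `target_completeness`, `contaminant_kmer_fraction`, and the underlying
#'   counts.
#' @export
evaluate_picking <- function(result, truth, target_id = "target",
                             target_genome = NULL, contaminant_genome = NULL,
                             k = 31) {
  picked <- picked_read_ids(result)
  missing <- setdiff(picked, truth$read_id)
  if (length(missing)) {
    stop("truth sidecar is missing picked read ids, e.g. ", missing[1])
  }
  origin <- truth$genome_id[match(picked, truth$read_id)]
  n_picked <- length(picked)
  n_picked_target <- sum(origin == target_id)
  universe <- c(result$universe_a_ids, result$universe_b_ids)
  u_origin <- truth$genome_id[match(universe, truth$read_id)]
  n_universe_target <- sum(u_origin == target_id, na.rm = TRUE)
  precision <- if (n_picked == 0L) NA_real_ else n_picked_target / n_picked
  recall <- if (n_universe_target == 0L) 0 else
    n_picked_target / n_universe_target

  completeness <- NA_real_
  contam <- NA_real_
  if (!is.null(target_genome)) {
    tseq <- if (inherits(target_genome, "SynGenome")) target_genome$sequence
            else target_genome
    xseq <- if (is.null(contaminant_genome)) character(0)
            else if (inherits(contaminant_genome, "SynGenome"))
              contaminant_genome$sequence
            else contaminant_genome
    cmp <- cpp_kmer_compare(result$final_assembly$contigs$sequence,
                            tseq, xseq, as.integer(k))
    completeness <- cmp$target_completeness
    contam <- cmp$contaminant_kmer_fraction
  }
  structure(list(precision = precision, recall = recall,
                 target_completeness = completeness,
                 contaminant_kmer_fraction = contam,
                 n_picked = n_picked, n_picked_target = n_picked_target,
                 n_universe_target = n_universe_target),
            class = "PickEval")
}

#' @export
print.PickEval <- function(x, ...) {
  cat(sprintf(
    "PickEval: precision %.4f, recall %.4f, completeness %.4f, contaminant %.4g\n",
    x$precision, x$recall, x$target_completeness,
    x$contaminant_kmer_fraction))
  invisible(x)
}

#' Paired-end scaffolding report
#'
#' Reports candidate contig junctions supported by mate pairs whose two
#' mates place on different contigs, sorted by support.  No joining is
#' performed: joining decisions are left to the analyst, as automated
#' closure would overclaim.
#'
#' @param assembly an `Assembly` whose placements include paired reads (ids
#'   ending `/1`, `/2`).
#' @return data frame (`contig_a`, `contig_b`, `n_pairs`, `orientation`),
#'   sorted by `n_pairs` descending; zero rows when no junctions are
#'   supported.
#' @export
scaffold_report <- function(assembly) {
  pl <- assembly$placements
  pl <- pl[is_mate(pl$read_id), , drop = FALSE]
  empty <- data.frame(contig_a = character(0), contig_b = character(0),
                      n_pairs = integer(0), orientation = character(0),
                      stringsAsFactors = FALSE)
  if (nrow(pl) == 0L) return(empty)
  pl$pair <- pair_base(pl$read_id)
  pl$mate <- sub("^.*/", "", pl$read_id)
  w <- stats::reshape(pl[, c("pair", "mate", "contig_id", "strand")],
                      idvar = "pair", timevar = "mate", direction = "wide")
  w <- w[!is.na(w$contig_id.1) & !is.na(w$contig_id.2) &
           w$contig_id.1 != w$contig_id.2, , drop = FALSE]
  if (nrow(w) == 0L) return(empty)
  swap <- w$contig_id.1 > w$contig_id.2
  a <- ifelse(swap, w$contig_id.2, w$contig_id.1)
  b <- ifelse(swap, w$contig_id.1, w$contig_id.2)
  ori <- ifelse(swap, paste0(w$strand.2, w$strand.1),
                paste0(w$strand.1, w$strand.2))
  tab <- stats::aggregate(list(n_pairs = a),
                          by = list(contig_a = a, contig_b = b,
                                    orientation = ori), FUN = length)
  tab <- tab[order(-tab$n_pairs, tab$contig_a, tab$contig_b), ,
             drop = FALSE]
  rownames(tab) <- NULL
  tab[, c("contig_a", "contig_b", "n_pairs", "orientation")]
}

#' Write a machine-readable pipeline run report
#'
#' @param result a `PickResult`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_pick_report <- function(result, path) {
  rep <- list(
    steps = result$counts,
    n_step3_picked = length(result$step3_picked_ids),
    n_step5_picked_pairs = length(result$step5_picked_pair_ids),
    n_step5_picked_singles = length(result$step5_picked_single_ids),
    n_final_contigs = nrow(result$final_assembly$contigs),
    final_assembly_bp = sum(nchar(result$final_assembly$contigs$sequence))
  )
  jsonlite::write_json(rep, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
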