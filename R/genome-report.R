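#' G+C content of a sequence
#'
#' @param sequence DNA string (ambiguity codes allowed; they count toward the
#'   denominator, not the G+C numerator).
#' @return list with `gc_bp` (count of G/C bases) and `gc_pct` (percentage of
#'   total length, rounded half-up to 2 decimals).
#' @export
gc_content <- function(sequence) {
  if (length(sequence) != 1L || nchar(sequence) == 0L) {
    stop("sequence must be a single non-empty string")
  }
  gc_bp <- nchar(gsub("[^GCgc]", "", sequence))
  list(gc_bp = gc_bp,
       gc_pct = round_half_up(100 * gc_bp / nchar(sequence), 2))
}

#' Coding base pairs of an annotated record
#'
#' Length of the strand-agnostic union of all CDS feature segments (overlaps
#' merged once), so the result is bounded by the genome size.
#'
#' @param record an `AnnotatedRecord` from [read_genbank_lite()].
#' @param union if `FALSE`, return the plain sum of CDS segment lengths
#'   instead of the merged union (for comparison).
#' @return coding length in bp (0 when the record has no CDS).
#' @export
coding_bp <- function(record, union = TRUE) {
  segs <- lapply(record$features, function(f) {
    if (f$type == "CDS") f$segments else NULL
  })
  segs <- do.call(rbind, segs)
  if (is.null(segs) || nrow(segs) == 0L) return(0L)
  if (!union) return(sum(segs[, 2] - segs[, 1] + 1L))
  ir <- IRanges::reduce(IRanges::IRanges(start = segs[, 1], end = segs[, 2]))
  sum(IRanges::width(ir))
}

#' Genome statistics from an annotated record
#'
#' Computes the annotation-independent genome statistics: size, G+C, coding
#' bases, and feature counts.  Percentages are relative to genome size and
#' rounded half-up to 2 decimals.
#'
#' @param record an `AnnotatedRecord`.
#' @return a `GenomeStats` list: `size`, `gc_bp`, `gc_pct`, `coding_bp`,
#'   `coding_pct`, `n_total_genes`, `n_cds`, `n_trna`, `n_rrna`, `n_tmrna`,
#'   `n_rna`, `n_pseudo`, `n_scaffolds`.
#' @export
genome_stats <- function(record) {
  types <- vapply(record$features, `[[`, "", "type")
  gc <- gc_content(record$sequence)
  cb <- coding_bp(record)
  n_cds <- sum(types == "CDS")
  n_trna <- sum(types == "tRNA")
  n_rrna <- sum(types == "rRNA")
  n_tmrna <- sum(types == "tmRNA")
  n_rna <- n_trna + n_rrna + n_tmrna
  n_pseudo <- sum(vapply(record$features, `[[`, logical(1), "pseudo"))
  structure(list(
    size = record$length,
    gc_bp = gc$gc_bp, gc_pct = gc$gc_pct,
    coding_bp = cb,
    coding_pct = round_half_up(100 * cb / record$length, 2),
    n_total_genes = n_cds + n_rna,
    n_cds = n_cds, n_trna = n_trna, n_rrna = n_rrna, n_tmrna = n_tmrna,
    n_rna = n_rna, n_pseudo = n_pseudo, n_scaffolds = 1L
  ), class = "GenomeStats")
}

#' @export
print.GenomeStats <- function(x, ...) {
  fmt <- function(v) format(v, big.mark = ",")
  rows <- rbind(
    c("Genome size (bp)", fmt(x$size), "100.00"),
    c("DNA coding (bp)", fmt(x$coding_bp), sprintf("%.2f", x$coding_pct)),
    c("DNA G+C (bp)", fmt(x$gc_bp), sprintf("%.2f", x$gc_pct)),
    c("DNA scaffolds", fmt(x$n_scaffolds), ""),
    c("Total genes", fmt(x$n_total_genes), "100.00"),
    c("Protein coding genes", fmt(x$n_cds),
      sprintf("%.2f", round_half_up(100 * x$n_cds /
                                      max(1, x$n_total_genes), 2))),
    c("RNA genes", fmt(x$n_rna),
      sprintf("%.2f", round_half_up(100 * x$n_rna /
                                      max(1, x$n_total_genes), 2))),
    c("Pseudo genes", fmt(x$n_pseudo), "")
  )
  cat(sprintf("%-24s %14s %8s\n", "Attribute", "Value", "% of total"))
  for (i in seq_len(nrow(rows))) {
    cat(sprintf("%-24s %14s %8s\n", rows[i, 1], rows[i, 2], rows[i, 3]))
  }
  invisible(x)
}
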