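#' Fragment a genome into fixed-length windows
#'
#' Consecutive non-overlapping windows of `fragment_len`; a final shorter
#' fragment is retained only if at least 100 bp.
#'
#' @param genome DNA string (or `SynGenome`).
#' @param fragment_len window length in bp (default 1020).
#' @return data frame with `start`, `end` (1-based inclusive), `sequence`.
#' @export
fragment_genome <- function(genome, fragment_len = 1020) {
  stopifnot(fragment_len > 0)
  seq <- if (inherits(genome, "SynGenome")) genome$sequence else genome
  L <- nchar(seq)
  starts <- seq.int(1L, L, by = fragment_len)
  ends <- pmin(starts + fragment_len - 1L, L)
  keep <- (ends - starts + 1L) >= pmin(fragment_len, 100L)
  starts <- starts[keep]; ends <- ends[keep]
  data.frame(start = starts, end = ends,
             sequence = substring(seq, starts, ends),
             stringsAsFactors = FALSE)
}

# Seed-and-extend local alignment of one fragment against a reference:
# k-mer voting locates the window and strand, then a local
# Smith-Waterman (blastn-like scoring 2/-3, gap open 5, extend 2) on the
# window yields identity and aligned length.
align_fragment <- function(frag, ref_index, ref_seq, submat) {
  a <- cpp_assign_reads(ref_index$ptr, frag, min_frac = 0.01)
  if (is.na(a$contig[1])) {
    return(list(aligned = FALSE, identity = NA_real_, coverage = NA_real_))
  }
  fl <- nchar(frag)
  L <- nchar(ref_seq)
  margin <- max(200L, as.integer(0.25 * fl))
  ws <- max(1L, a$start[1] - margin)
  we <- min(L, a$start[1] + fl + margin)
  window <- substr(ref_seq, ws, we)
  qry <- if (a$strand[1] == "-") revcomp(frag) else frag
  aln <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAString(qry),
    subject = Biostrings::DNAString(window),
    type = "local", substitutionMatrix = submat,
    gapOpening = 5, gapExtension = 2)
  pat <- as.character(Biostrings::pattern(aln))
  identity <- Biostrings::pid(aln, type = "PID1")
  coverage <- nchar(gsub("-", "", pat)) / fl
  list(aligned = TRUE, identity = identity, coverage = coverage)
}

#' ANIb average nucleotide identity
#'
#' Computes ANIb between a query and a reference genome: the query is cut
#' into `fragment_len` windows ([fragment_genome()]), each fragment is
#' locally aligned to the reference on either strand, weak hits are
#' discarded (identity below `min_identity` percent or alignment covering
#' less than `min_coverage` of the fragment), and the mean identity of the
#' retained fragments' best hits is reported.  The 95-96 percent region of
#' the resulting scale approximates the bacterial species boundary.
#'
#' @param query_genome,reference_genome DNA strings (or `SynGenome`).
#' @param fragment_len fragment length, bp (default 1020).
#' @param min_identity retention threshold on percent identity (default 30).
#' @param min_coverage retention threshold on the aligned fraction of the
#'   fragment (default 0.7).
#' @param seed_k k-mer size used to seed alignments (default 15).
#' @return an `AniResult`: list with `ani_pct` (`NA` if no fragment is
#'   retained), `n_fragments_total`, `n_fragments_aligned`, and a
#'   per-fragment table `fragments` (`start`, `end`, `identity`, `coverage`,
#'   `retained`).
#' @export
anib <- function(query_genome, reference_genome, fragment_len = 1020,
                 min_identity = 30, min_coverage = 0.7, seed_k = 15) {
  qseq <- if (inherits(query_genome, "SynGenome")) query_genome$sequence
          else query_genome
  rseq <- if (inherits(reference_genome, "SynGenome"))
            reference_genome$sequence else reference_genome
  stopifnot(nchar(qseq) > 0, nchar(rseq) > 0)
  frags <- fragment_genome(qseq, fragment_len)
  idx <- build_index(rseq, k = seed_k)
  submat <- Biostrings::nucleotideSubstitutionMatrix(match = 2,
                                                     mismatch = -3)
  res <- lapply(frags$sequence, align_fragment, ref_index = idx,
                ref_seq = rseq, submat = submat)
  frags$identity <- vapply(res, `[[`, numeric(1), "identity")
  frags$coverage <- vapply(res, `[[`, numeric(1), "coverage")
  frags$retained <- !is.na(frags$identity) &
    frags$identity >= min_identity & frags$coverage >= min_coverage
  ani <- if (any(frags$retained)) {
    round_half_up(mean(frags$identity[frags$retained]), 2)
  } else NA_real_
  structure(list(ani_pct = ani,
                 n_fragments_total = nrow(frags),
                 n_fragments_aligned = sum(frags$retained),
                 fragments = frags[, c("start", "end", "identity",
                                       "coverage", "retained")]),
            class = "AniResult")
}

#' @export
print.AniResult <- function(x, ...) {
  cat(sprintf("AniResult: ANIb = %s%% (%d/%d fragments retained)\n",
              ifelse(is.na(x$ani_pct), "NA", sprintf("%.2f", x$ani_pct)),
              x$n_fragments_aligned, x$n_fragments_total))
  invisible(x)
}
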