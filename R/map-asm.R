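#' Assemble reads into contigs with read placements
#'
#' A minimal de Bruijn assembler: builds a graph over canonical k-mers seen
#' at least `min_kmer_count` times, clips tips shorter than `tip_max_len`,
#' and emits maximal non-branching paths (unitigs) of length >= 2k as
#' contigs.  Every input read is then placed back onto the contigs by k-mer
#' voting ([assign_read()]), and the placements are stored with the
#' assembly.  Deterministic: an identical read multiset with identical
#' parameters yields an identical assembly.
#'
#' @param reads read data frame (column `sequence`; `id` used for
#'   placements).
#' @param k odd k-mer size (<= 31); must be below the length of usable reads.
#' @param min_kmer_count minimum k-mer multiplicity retained (use 1 for
#'   low-coverage data).
#' @param tip_max_len tips shorter than this many bp are clipped (default 2k).
#' @param min_frac minimum matched k-mer fraction for read placement.
#' @param auto_min_count if `TRUE`, raise `min_kmer_count` to the valley of
#'   the k-mer multiplicity histogram when a clear coverage peak exists
#'   (the classical coverage-cutoff rule).  At high depth, error k-mers
#'   recur by coincidence and a fixed cutoff of 2 leaves branch points in
#'   the graph; the valley rule removes them while never engaging on
#'   low-coverage or error-free input.
#' @return an `Assembly`: list with `contigs` (data frame `id`, `sequence`,
#'   `mean_coverage`) and `placements` (data frame `read_id`, `contig_id`,
#'   `start`, `strand`, `frac`; unplaced reads are absent).
#' @export
assemble <- function(reads, k = 31, min_kmer_count = 2, tip_max_len = 2 * k,
                     min_frac = 0.5, auto_min_count = FALSE) {
  stopifnot(k %% 2 == 1, k >= 3, k <= 31)
  if (nrow(reads) == 0L) {
    return(new_assembly(data.frame(id = character(0), sequence = character(0),
                                   mean_coverage = numeric(0),
                                   stringsAsFactors = FALSE),
                        empty_placements()))
  }
  usable <- nchar(reads$sequence) > k
  if (!any(usable)) {
    stop("k (", k, ") is not below the length of any read")
  }
  asm <- cpp_assemble(reads$sequence[usable], as.integer(k),
                      as.integer(min_kmer_count), as.integer(tip_max_len),
                      isTRUE(auto_min_count))
  contigs <- data.frame(
    id = if (length(asm$sequence)) sprintf("c%04d", seq_along(asm$sequence))
         else character(0),
    sequence = as.character(asm$sequence),
    mean_coverage = as.numeric(asm$coverage),
    stringsAsFactors = FALSE)
  if (nrow(contigs) == 0L) {
    return(new_assembly(contigs, empty_placements()))
  }
  idx <- build_index(contigs, k)
  pl <- assign_read(reads, idx, min_frac = min_frac)
  new_assembly(contigs, pl)
}

new_assembly <- function(contigs, placements) {
  structure(list(contigs = contigs, placements = placements),
            class = "Assembly")
}

empty_placements <- function() {
  data.frame(read_id = character(0), contig_id = character(0),
             start = integer(0), strand = character(0), frac = numeric(0),
             stringsAsFactors = FALSE)
}

#' @export
print.Assembly <- function(x, ...) {
  cat("Assembly:", nrow(x$contigs), "contigs (",
      format(sum(nchar(x$contigs$sequence)), big.mark = ","), "bp ),",
      nrow(x$placements), "read placements\n")
  invisible(x)
}

#' Build a canonical k-mer index over contigs
#'
#' Indexes every k-mer occurrence of every contig under its canonical form
#' (the lexicographic minimum of the k-mer and its reverse complement).
#'
#' @param contigs contig data frame (`id`, `sequence`) or character vector.
#' @param k odd k-mer size (<= 31).
#' @return a `KmerIndex` (external pointer plus contig ids).
#' @export
build_index <- function(contigs, k = 21) {
  if (is.character(contigs)) {
    contigs <- data.frame(id = if (is.null(names(contigs)))
                            sprintf("c%04d", seq_along(contigs))
                          else names(contigs),
                          sequence = unname(contigs),
                          stringsAsFactors = FALSE)
  }
  stopifnot(nrow(contigs) > 0, k %% 2 == 1, k >= 3, k <= 31)
  structure(list(ptr = cpp_build_index(contigs$sequence, as.integer(k)),
                 contig_ids = contigs$id, k = as.integer(k)),
            class = "KmerIndex")
}

#' Look up a k-mer in a `KmerIndex`
#'
#' @param index a [build_index()] result.
#' @param kmer a k-length DNA string.
#' @return data frame of occurrences (`contig_id`, `pos`, `strand`); zero
#'   rows when absent.
#' @export
index_lookup <- function(index, kmer) {
  h <- cpp_index_lookup(index$ptr, kmer)
  if (length(h) == 0L || length(h$contig) == 0L) {
    return(data.frame(contig_id = character(0), pos = integer(0),
                      strand = character(0), stringsAsFactors = FALSE))
  }
  data.frame(contig_id = index$contig_ids[h$contig], pos = h$pos,
             strand = h$strand, stringsAsFactors = FALSE)
}

#' Assign reads to contigs by k-mer voting
#'
#' Counts each read's k-mers hitting each contig on a consistent strand and
#' assigns the read to the contig with the highest hit fraction, provided
#' that fraction reaches `min_frac`.  Ties are left unassigned
#' (conservative).  Chimeric bait reads may legitimately match via only part
#' of their length, which is why bait mapping uses a lower `min_frac` than
#' direct-shotgun placement.
#'
#' @param reads read data frame (or character vector of sequences).
#' @param index a [build_index()] result.
#' @param min_frac minimum matched k-mer fraction.
#' @return placement data frame (`read_id`, `contig_id`, `start`, `strand`,
#'   `frac`); unassigned reads are omitted.
#' @export
assign_read <- function(reads, index, min_frac = 0.5) {
  if (is.character(reads)) {
    reads <- data.frame(id = sprintf("r%06d", seq_along(reads)),
                        sequence = reads, stringsAsFactors = FALSE)
  }
  if (nrow(reads) == 0L) return(empty_placements())
  a <- cpp_assign_reads(index$ptr, reads$sequence, min_frac)
  hit <- !is.na(a$contig)
  data.frame(read_id = reads$id[hit],
             contig_id = index$contig_ids[a$contig[hit]],
             start = a$start[hit],
             strand = a$strand[hit],
             frac = a$frac[hit],
             stringsAsFactors = FALSE)
}

#' Write contigs to FASTA
#'
#' @param assembly an `Assembly`.
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
write_contigs <- function(assembly, path) {
  df <- assembly$contigs
  df$description <- sprintf("length=%d coverage=%.1f", nchar(df$sequence),
                            df$mean_coverage)
  write_fasta(df, path)
}
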