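#' Detect CRISPR direct-repeat/spacer arrays
#'
#' Scans the forward strand of a genome for CRISPR arrays: a direct repeat
#' of 23-55 bp occurring at least `min_copies` times, with copies diverging
#' from the consensus by at most `max_divergence` (degenerate terminal
#' copies allowed up to `terminal_divergence`), spacer lengths within
#' `spacer_ratio` times the repeat length, and spacers mutually dissimilar:
#' a candidate is rejected when more than 20 percent of spacer pairs reach
#' `spacer_max_identity` (5'-aligned identity), which screens out
#' tandem-like arrays while tolerating isolated chance collisions between
#' short random spacers.  Candidates are seeded by exact `seed_k`-mer
#' triples with compliant spacing and extended to the full repeat by
#' column-conservation, with boundary polishing and consensus-guided repair
#' of skipped interior copies; overlapping candidates are resolved by
#' keeping the one with more repeats, then the longer span.
#'
#' @param genome DNA string (or `SynGenome`, or `AnnotatedRecord`).
#' @param repeat_range allowed direct-repeat lengths, bp (default 23-55).
#' @param min_copies minimum number of repeat copies (default 3).
#' @param max_divergence maximum per-copy divergence from the consensus for
#'   internal copies (default 0.2).
#' @param terminal_divergence divergence allowed for terminal copies
#'   (default 1/3).
#' @param spacer_ratio allowed spacer length as a multiple of the repeat
#'   length (default c(0.6, 2.5)).
#' @param spacer_max_identity spacers with pairwise identity at or above
#'   this are considered tandem-like and the candidate is rejected
#'   (default 0.6).
#' @param seed_k exact-match seed length (default 23, the minimum repeat).
#' @return list of `CrisprArray` objects, ordered by genomic position.
#'   Each has `start`, `end` (1-based, first repeat start to last repeat
#'   end), `repeats` and `spacers` (data frames with `position`,
#'   `sequence`), `consensus_repeat`, `n_spacers`, and `conservation` (the
#'   per-column majority fraction).
#' @export
find_arrays <- function(genome, repeat_range = c(23L, 55L), min_copies = 3L,
                        max_divergence = 0.2, terminal_divergence = 1 / 3,
                        spacer_ratio = c(0.6, 2.5),
                        spacer_max_identity = 0.6, seed_k = 23L) {
  seq <- if (inherits(genome, "SynGenome")) genome$sequence
         else if (inherits(genome, "AnnotatedRecord")) genome$sequence
         else genome
  stopifnot(nchar(seq) > 0)
  L <- nchar(seq)
  if (L < seed_k * min_copies) return(list())

  # seed: positions of k-mers occurring >= min_copies times, grouped into
  # runs with compliant consecutive spacing
  starts <- seq_len(L - seed_k + 1L)
  kmers <- substring(seq, starts, starts + seed_k - 1L)
  ok <- !grepl("[^ACGT]", kmers)
  tab <- table(kmers[ok])
  cand_kmers <- names(tab)[tab >= min_copies]
  if (length(cand_kmers) == 0L) return(list())

  gap_min <- floor(repeat_range[1] * (1 + spacer_ratio[1]))
  gap_max <- ceiling(repeat_range[2] * (1 + spacer_ratio[2]))

  candidates <- list()
  for (km in cand_kmers) {
    pos <- starts[ok][kmers[ok] == km]
    if (length(pos) < min_copies) next
    pos <- sort(pos)
    gaps <- diff(pos)
    compliant <- gaps >= gap_min & gaps <= gap_max
    # maximal runs of compliant gaps
    r <- rle(compliant)
    idx_end <- cumsum(r$lengths)
    idx_start <- idx_end - r$lengths + 1L
    for (ri in which(r$values & r$lengths >= min_copies - 1L)) {
      run_pos <- pos[idx_start[ri]:(idx_end[ri] + 1L)]
      cand <- extend_candidate(seq, run_pos, seed_k, repeat_range,
                               min_copies, max_divergence,
                               terminal_divergence, spacer_ratio,
                               spacer_max_identity)
      if (!is.null(cand)) {
        candidates[[length(candidates) + 1L]] <- cand
      }
    }
  }
  if (length(candidates) == 0L) return(list())

  # overlap resolution: more repeats first, then longer span
  nrep <- vapply(candidates, function(a) nrow(a$repeats), integer(1))
  span <- vapply(candidates, function(a) a$end - a$start + 1L, integer(1))
  ordc <- order(-nrep, -span)
  kept <- list()
  for (i in ordc) {
    a <- candidates[[i]]
    overlaps <- any(vapply(kept, function(b) {
      a$start <= b$end && b$start <= a$end
    }, logical(1)))
    if (!overlaps) kept[[length(kept) + 1L]] <- a
  }
  kept[order(vapply(kept, `[[`, integer(1), "start"))]
}

# Extend a run of exact seed positions to the full repeat unit and validate
# the array rules; returns a CrisprArray or NULL.
extend_candidate <- function(seq, pos, seed_k, repeat_range, min_copies,
                             max_divergence, terminal_divergence,
                             spacer_ratio, spacer_max_identity) {
  n <- length(pos)
  gaps <- diff(pos)
  max_len <- min(repeat_range[2], min(gaps))  # repeats must not overlap

  col_at <- function(off) substring(seq, pos + off, pos + off)
  # a column belongs to the repeat when at least 90% of copies agree
  # (rounded up, so small arrays require unanimity; random flanking or
  # spacer columns agree with probability far below this)
  conserved <- function(cols) {
    t <- table(cols[cols %in% c("A", "C", "G", "T")])
    if (length(t) == 0L) return(FALSE)
    max(t) >= ceiling(0.9 * length(cols))
  }
  # extend left
  left <- 0L
  while (seed_k + left < max_len && pos[1] - left - 1L >= 1L &&
         conserved(col_at(-left - 1L))) {
    left <- left + 1L
  }
  # extend right
  right <- 0L
  while (seed_k + left + right < max_len &&
         pos[n] + seed_k + right <= nchar(seq) &&
         conserved(col_at(seed_k + right))) {
    right <- right + 1L
  }
  rep_len <- seed_k + left + right
  if (rep_len < repeat_range[1] || rep_len > repeat_range[2]) return(NULL)
  rep_start <- pos - left
  reps <- substring(seq, rep_start, rep_start + rep_len - 1L)

  cons <- consensus_repeat(reps)
  div <- vapply(reps, function(r) hamming_frac(r, cons), numeric(1))
  # trim terminal copies that exceed even the relaxed terminal allowance
  while (length(reps) > min_copies && div[1] > terminal_divergence) {
    reps <- reps[-1]; rep_start <- rep_start[-1]; div <- div[-1]
  }
  while (length(reps) > min_copies && div[length(div)] > terminal_divergence) {
    reps <- reps[-length(reps)]; rep_start <- rep_start[-length(rep_start)]
    div <- div[-length(div)]
  }
  n <- length(reps)
  if (n < min_copies) return(NULL)
  internal <- if (n > 2L) div[2:(n - 1L)] else numeric(0)
  if (any(internal > max_divergence)) return(NULL)
  if (div[1] > terminal_divergence || div[n] > terminal_divergence) {
    return(NULL)
  }

  sp_start <- rep_start[-n] + rep_len
  sp_end <- rep_start[-1] - 1L
  sp_len <- sp_end - sp_start + 1L
  if (any(sp_len < floor(spacer_ratio[1] * rep_len)) ||
      any(sp_len > ceiling(spacer_ratio[2] * rep_len))) {
    return(NULL)
  }
  spacers <- substring(seq, sp_start, sp_end)
  # mutual dissimilarity as a set property: tandem-like arrays have most
  # pairs near-identical, while isolated chance collisions between short
  # random spacers are tolerated
  if (length(spacers) > 1L) {
    pairs <- utils::combn(length(spacers), 2L)
    ident <- apply(pairs, 2L, function(ij)
      seq_identity(spacers[ij[1]], spacers[ij[2]]))
    if (mean(ident >= spacer_max_identity) > 0.2) return(NULL)
  }

  # degenerate terminal copies: exact seeding cannot reach a worn first or
  # last copy, so scan beyond each end, at compliant spacer distances, for a
  # window within terminal_divergence of the consensus
  cons <- consensus_repeat(reps)
  lo_sp <- floor(spacer_ratio[1] * rep_len)
  hi_sp <- ceiling(spacer_ratio[2] * rep_len)
  scan_copy <- function(range_starts) {
    best <- NULL
    for (s in range_starts) {
      if (s < 1L || s + rep_len - 1L > nchar(seq)) next
      d <- hamming_frac(substring(seq, s, s + rep_len - 1L), cons)
      if (d <= terminal_divergence && (is.null(best) || d < best$d)) {
        best <- list(s = s, d = d)
      }
    }
    best
  }
  spacer_ok <- function(sp) {
    mean(vapply(spacers, function(x)
      seq_identity(sp, x) >= spacer_max_identity, logical(1))) <= 0.2
  }
  repeat {
    lead <- scan_copy(seq.int(rep_start[1] - rep_len - hi_sp,
                              rep_start[1] - rep_len - lo_sp))
    if (is.null(lead)) break
    new_sp <- substring(seq, lead$s + rep_len, rep_start[1] - 1L)
    if (!spacer_ok(new_sp)) break
    rep_start <- c(lead$s, rep_start)
    reps <- c(substring(seq, lead$s, lead$s + rep_len - 1L), reps)
    spacers <- c(new_sp, spacers)
  }
  repeat {
    last_end <- rep_start[length(rep_start)] + rep_len - 1L
    trail <- scan_copy(seq.int(last_end + 1L + lo_sp,
                               last_end + 1L + hi_sp))
    if (is.null(trail)) break
    new_sp <- substring(seq, last_end + 1L, trail$s - 1L)
    if (!spacer_ok(new_sp)) break
    rep_start <- c(rep_start, trail$s)
    reps <- c(reps, substring(seq, trail$s, trail$s + rep_len - 1L))
    spacers <- c(spacers, new_sp)
  }
  # boundary polish: seeds drawn from a subset of copies that share a
  # chance flanking base can drag one junk column into the repeat; strip
  # terminal columns whose conservation over the full copy set falls below
  # the level a repeat column must sustain
  repeat {
    consv <- column_conservation(reps)
    strip_l <- consv[1] < 0.8
    strip_r <- consv[length(consv)] < 0.8
    if ((!strip_l && !strip_r) || rep_len <= repeat_range[1]) break
    if (strip_l) {
      rep_start <- rep_start + 1L
      rep_len <- rep_len - 1L
    }
    if (strip_r && rep_len > repeat_range[1]) rep_len <- rep_len - 1L
    if (rep_len < repeat_range[1]) return(NULL)
    reps <- substring(seq, rep_start, rep_start + rep_len - 1L)
  }
  # internal repair: a seed run drawn from a subset of copies can skip an
  # interior copy entirely (its neighbourhood lacked the seed); fill gaps
  # wider than the allowed spacer with the best consensus match inside them
  cons <- consensus_repeat(reps)
  lo_sp <- floor(spacer_ratio[1] * rep_len)
  hi_sp <- ceiling(spacer_ratio[2] * rep_len)
  i <- 1L
  while (i < length(rep_start)) {
    gap <- rep_start[i + 1L] - (rep_start[i] + rep_len)
    if (gap > hi_sp) {
      from <- rep_start[i] + rep_len + lo_sp
      to <- min(rep_start[i + 1L] - rep_len - lo_sp,
                rep_start[i] + rep_len + hi_sp)
      hit <- NULL
      if (from <= to) {
        for (s in seq.int(from, to)) {
          d <- hamming_frac(substring(seq, s, s + rep_len - 1L), cons)
          if (d <= max_divergence && (is.null(hit) || d < hit$d)) {
            hit <- list(s = s, d = d)
          }
        }
      }
      if (is.null(hit)) return(NULL)  # irreparable over-long spacer
      rep_start <- append(rep_start, hit$s, after = i)
      reps <- substring(seq, rep_start, rep_start + rep_len - 1L)
    } else {
      i <- i + 1L
    }
  }
  n <- length(reps)
  if (n < min_copies) return(NULL)
  sp_start <- rep_start[-n] + rep_len
  spacers <- substring(seq, sp_start, rep_start[-1] - 1L)
  sp_len <- nchar(spacers)
  if (any(sp_len < lo_sp) || any(sp_len > hi_sp)) return(NULL)

  cons <- consensus_repeat(reps)
  consv <- column_conservation(reps)
  structure(list(
    start = rep_start[1],
    end = rep_start[n] + rep_len - 1L,
    repeats = data.frame(position = rep_start, sequence = unname(reps),
                         stringsAsFactors = FALSE),
    spacers = data.frame(position = sp_start, sequence = unname(spacers),
                         stringsAsFactors = FALSE),
    consensus_repeat = cons,
    n_spacers = length(spacers),
    conservation = consv
  ), class = "CrisprArray")
}

hamming_frac <- function(a, b) {
  va <- strsplit(a, "")[[1]]
  vb <- strsplit(b, "")[[1]]
  m <- min(length(va), length(vb))
  (sum(va[seq_len(m)] != vb[seq_len(m)]) +
     abs(length(va) - length(vb))) / max(length(va), length(vb))
}

# Pairwise identity used for spacer dissimilarity: 5'-aligned matched
# positions over the longer length.  The rule screens out tandem-repeat
# "spacers" (near-copies score ~1) while unrelated random spacers score
# around 0.25, comfortably below any sensible threshold; an edit-distance
# identity would put random pairs near 0.5 and misfire on short spacers.
seq_identity <- function(a, b) {
  ml <- max(nchar(a), nchar(b))
  if (ml == 0L) return(1)
  m <- min(nchar(a), nchar(b))
  va <- strsplit(a, "")[[1]][seq_len(m)]
  vb <- strsplit(b, "")[[1]][seq_len(m)]
  sum(va == vb) / ml
}

#' Consensus of repeat copies
#'
#' Per-column majority base across the repeat copies; ties become IUPAC
#' ambiguity codes.  Copies of unequal length are aligned by their 5' ends,
#' and trailing columns are only reported while at least half the copies
#' reach them.
#'
#' @param x a `CrisprArray`, or a character vector of repeat copies.
#' @return the consensus DNA string (uppercase).
#' @export
consensus_repeat <- function(x) {
  reps <- if (inherits(x, "CrisprArray")) x$repeats$sequence else x
  stopifnot(length(reps) >= 1L)
  n <- length(reps)
  maxl <- max(nchar(reps))
  out <- character(0)
  for (col in seq_len(maxl)) {
    bases <- substring(reps, col, col)
    bases <- bases[nzchar(bases)]
    if (length(bases) < n / 2) break  # trailing-column occupancy rule
    t <- table(bases)
    top <- names(t)[t == max(t)]
    out <- c(out, if (length(top) == 1L) top
             else Biostrings::mergeIUPACLetters(paste(sort(top),
                                                      collapse = "")))
  }
  paste(out, collapse = "")
}

column_conservation <- function(reps) {
  maxl <- max(nchar(reps))
  vapply(seq_len(maxl), function(col) {
    bases <- substring(reps, col, col)
    bases <- bases[nzchar(bases)]
    if (length(bases) == 0L) return(0)
    max(table(bases)) / length(bases)
  }, numeric(1))
}

#' @export
print.CrisprArray <- function(x, ...) {
  cat(sprintf(
    "CrisprArray %s..%s: %d repeats / %d spacers, consensus %s\n",
    format(x$start, big.mark = ","), format(x$end, big.mark = ","),
    nrow(x$repeats), x$n_spacers, x$consensus_repeat))
  invisible(x)
}

#' Export CRISPR arrays as GFF3 feature lines
#'
#' @param arrays list of `CrisprArray`.
#' @param seqid sequence identifier for column 1.
#' @return character vector of GFF3 lines (with header pragma).
#' @export
crispr_gff3 <- function(arrays, seqid = "genome") {
  lines <- "##gff-version 3"
  for (ai in seq_along(arrays)) {
    a <- arrays[[ai]]
    lines <- c(lines, sprintf(
      "%s\tdiffpickr\trepeat_region\t%d\t%d\t.\t+\t.\tID=crispr%d;Note=CRISPR array;consensus=%s",
      seqid, a$start, a$end, ai, a$consensus_repeat))
    for (i in seq_len(nrow(a$repeats))) {
      lines <- c(lines, sprintf(
        "%s\tdiffpickr\tdirect_repeat\t%d\t%d\t.\t+\t.\tParent=crispr%d",
        seqid, a$repeats$position[i],
        a$repeats$position[i] + nchar(a$repeats$sequence[i]) - 1L, ai))
    }
    for (i in seq_len(nrow(a$spacers))) {
      lines <- c(lines, sprintf(
        "%s\tdiffpickr\tbinding_site\t%d\t%d\t.\t+\t.\tParent=crispr%d;Note=spacer",
        seqid, a$spacers$position[i],
        a$spacers$position[i] + nchar(a$spacers$sequence[i]) - 1L, ai))
    }
  }
  lines
}
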