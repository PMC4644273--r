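# Independent brute-force oracles and fixture builders used across the suite.
# These deliberately avoid the package's own implementation paths.

random_dna <- function(n, seed = NULL, alphabet = c("A", "C", "G", "T")) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

oracle_revcomp <- function(s) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

# step-by-step sliding-window trim: explicit window walk over the quality
# string, independent of the C++ implementation
oracle_trim <- function(qual_scores, q_threshold, window_frac) {
  L <- length(qual_scores)
  if (L == 0L) return(NULL)
  w <- max(1L, floor(window_frac * L + 0.5))  # round half away from zero
  if (w > L) w <- L
  nwin <- L - w + 1L
  good <- NA
  for (s in seq_len(nwin)) {
    if (mean(qual_scores[s:(s + w - 1L)]) >= q_threshold) { good <- s; break }
  }
  if (is.na(good)) return(NULL)
  bad <- NA
  if (good < nwin) {
    for (s in (good + 1L):nwin) {
      if (mean(qual_scores[s:(s + w - 1L)]) < q_threshold) { bad <- s; break }
    }
  }
  c(start = good, end = if (is.na(bad)) L else bad - 1L)
}

# every k-mer of a sequence, canonicalised, as a character vector
oracle_kmers <- function(s, k) {
  if (nchar(s) < k) return(character(0))
  kk <- substring(s, seq_len(nchar(s) - k + 1L), seq_len(nchar(s) - k + 1L) + k - 1L)
  kk <- kk[!grepl("[^ACGT]", kk)]
  rc <- vapply(kk, oracle_revcomp, "", USE.NAMES = FALSE)
  pmin(kk, rc)
}

# brute-force read assignment: count canonical k-mer hits per contig/strand
oracle_assign <- function(read_seq, contigs, k, min_frac) {
  rks <- substring(read_seq, seq_len(nchar(read_seq) - k + 1L),
                   seq_len(nchar(read_seq) - k + 1L) + k - 1L)
  rks <- rks[!grepl("[^ACGT]", rks)]
  if (length(rks) == 0L) return(NULL)
  votes <- list()
  for (ci in seq_along(contigs)) {
    cseq <- contigs[ci]
    cks <- substring(cseq, seq_len(nchar(cseq) - k + 1L),
                     seq_len(nchar(cseq) - k + 1L) + k - 1L)
    cks_rc <- vapply(cks, oracle_revcomp, "", USE.NAMES = FALSE)
    # strand +: read k-mer matches contig forward, or read rc matches
    plus <- sum(rks %in% cks)
    minus <- sum(vapply(rks, oracle_revcomp, "", USE.NAMES = FALSE) %in% cks)
    votes[[paste0(ci, "+")]] <- plus
    votes[[paste0(ci, "-")]] <- minus
  }
  v <- unlist(votes)
  best <- max(v)
  if (best / length(rks) < min_frac) return(NULL)
  if (sum(v == best) > 1L) return(NULL)
  key <- names(v)[which.max(v)]
  list(contig = as.integer(substr(key, 1, nchar(key) - 1L)),
       strand = substr(key, nchar(key), nchar(key)),
       frac = best / length(rks))
}

# mutate a sequence with substitutions at recorded positions
mutate_with_positions <- function(s, rate, seed) {
  set.seed(seed)
  v <- strsplit(s, "")[[1]]
  pos <- which(runif(length(v)) < rate)
  for (p in pos) {
    v[p] <- sample(setdiff(c("A", "C", "G", "T"), v[p]), 1)
  }
  list(sequence = paste(v, collapse = ""), positions = pos)
}

# plant a CRISPR array (repeat copies separated by distinct random spacers)
# inside random flanks; returns the sequence and the ground truth
plant_crispr <- function(repeat_seq, n_spacers, spacer_len, flank = 3000,
                         seed = 1) {
  set.seed(seed)
  if (length(spacer_len) == 1L) spacer_len <- rep(spacer_len, n_spacers)
  spacers <- vapply(spacer_len, function(l) random_dna(l), "")
  left <- random_dna(flank)
  right <- random_dna(flank)
  body <- repeat_seq
  for (i in seq_len(n_spacers)) {
    body <- paste0(body, spacers[i], repeat_seq)
  }
  list(sequence = paste0(left, body, right),
       array_start = flank + 1L,
       array_end = flank + nchar(body),
       n_repeats = n_spacers + 1L,
       n_spacers = n_spacers,
       repeat_seq = repeat_seq,
       spacers = spacers)
}

# small read table builder
make_reads <- function(seqs, quals = NULL, ids = NULL, platform = NA) {
  n <- length(seqs)
  if (n == 0L) {
    return(data.frame(id = character(0), platform = character(0),
                      sequence = character(0), quality = character(0),
                      mate_id = character(0), stringsAsFactors = FALSE))
  }
  if (is.null(quals)) quals <- vapply(nchar(seqs), function(l)
    paste(rep("I", l), collapse = ""), "")
  if (is.null(ids)) ids <- sprintf("r%04d", seq_len(n))
  data.frame(id = ids, platform = platform, sequence = seqs, quality = quals,
             mate_id = NA_character_, stringsAsFactors = FALSE)
}

empty_pl <- function() data.frame(read_id = character(0),
                                  contig_id = character(0),
                                  start = integer(0), strand = character(0),
                                  frac = numeric(0), stringsAsFactors = FALSE)

phred_string <- function(scores) intToUtf8(scores + 33L)

# a small synthetic GenBank flat file written from parts
write_toy_genbank <- function(path, sequence, features,
                              locus = "TOYREC01") {
  L <- nchar(sequence)
  lines <- c(sprintf("LOCUS       %-17s %6d bp    DNA     circular BCT 01-JAN-2020",
                     locus, L),
             "DEFINITION  synthetic toy record.",
             sprintf("ACCESSION   %s", locus),
             "FEATURES             Location/Qualifiers",
             sprintf("     source          1..%d", L),
             "                     /organism=\"synthetic construct\"")
  for (f in features) {
    lines <- c(lines, sprintf("     %-15s %s", f$key, f$location))
    for (q in f$qualifiers) lines <- c(lines, paste0("                     ", q))
  }
  lines <- c(lines, "ORIGIN")
  for (i in seq(1, L, by = 60)) {
    chunk <- substr(sequence, i, min(i + 59, L))
    groups <- substring(chunk, seq(1, nchar(chunk), 10),
                        pmin(seq(1, nchar(chunk), 10) + 9, nchar(chunk)))
    lines <- c(lines, sprintf("%9d %s", i, paste(tolower(groups),
                                                 collapse = " ")))
  }
  lines <- c(lines, "//")
  writeLines(lines, path)
  path
}
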