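test_that("error-free tiling reads reassemble the exact genome", {
  # seed-fixed 5 kb genome verified (brute force) to be free of duplicate
  # 31-mers, tiled by 200 bp reads every 50 bp
  g <- generate_genome(5000, 0.5, seed = 42, circular = FALSE)
  expect_false(any(duplicated(oracle_kmers(g$sequence, 31))))
  starts <- seq(1, 4801, by = 50)
  reads <- make_reads(substring(g$sequence, starts, starts + 199))
  asm <- assemble(reads, k = 31, min_kmer_count = 1, min_frac = 0.5)
  expect_equal(nrow(asm$contigs), 1L)
  expect_true(asm$contigs$sequence[1] %in%
                c(g$sequence, oracle_revcomp(g$sequence)))
  # with error rate 0 every read is placed (assign_read property)
  expect_equal(sort(asm$placements$read_id), sort(reads$id))
  expect_true(all(asm$placements$frac == 1))
})

test_that("reads from disjoint genomes never co-assemble into one contig", {
  g1 <- generate_genome(4000, 0.5, seed = 51, circular = FALSE)
  g2 <- generate_genome(4000, 0.5, seed = 52, circular = FALSE)
  k1 <- unique(oracle_kmers(g1$sequence, 31))
  k2 <- unique(oracle_kmers(g2$sequence, 31))
  expect_length(intersect(k1, k2), 0)
  tile <- function(g) substring(g$sequence, seq(1, 3801, 40),
                                seq(1, 3801, 40) + 199)
  reads <- make_reads(c(tile(g1), tile(g2)))
  asm <- assemble(reads, k = 31, min_kmer_count = 1)
  expect_equal(nrow(asm$contigs), 2L)
  for (cs in asm$contigs$sequence) {
    ck <- unique(oracle_kmers(cs, 31))
    from1 <- any(ck %in% k1)
    from2 <- any(ck %in% k2)
    expect_false(from1 && from2)
  }
})

test_that("assembly is deterministic and rejects unusable k", {
  g <- generate_genome(3000, 0.5, seed = 53, circular = FALSE)
  starts <- seq(1, 2801, by = 30)
  reads <- make_reads(substring(g$sequence, starts, starts + 149))
  a1 <- assemble(reads, k = 31, min_kmer_count = 1)
  # shuffled read order, same multiset
  a2 <- assemble(reads[rev(seq_len(nrow(reads))), ], k = 31,
                 min_kmer_count = 1)
  expect_identical(a1$contigs$sequence, a2$contigs$sequence)

  short <- make_reads(replicate(5, random_dna(30)))
  expect_error(assemble(short, k = 31), "k")
  empty <- make_reads(character(0))
  expect_equal(nrow(assemble(empty, k = 31)$contigs), 0L)
})

test_that("k-mer index counts occurrences and resolves lookups", {
  idx <- build_index(c(c1 = "ACGTACGT"), k = 5)
  # all L - k + 1 = 4 positions indexed, across the distinct canonical forms
  kmers5 <- substring("ACGTACGT", 1:4, 5:8)
  pos <- unique(do.call(rbind, lapply(kmers5, index_lookup, index = idx)))
  expect_equal(nrow(pos), 4L)
  hits <- index_lookup(idx, "ACGTA")
  expect_equal(nrow(hits), 2L)  # occurs at 1 and (canonically, rc) at 4
  expect_true(all(hits$contig_id == "c1"))

  g <- generate_genome(2000, 0.5, seed = 54, circular = FALSE)
  idx2 <- build_index(c(g1 = g$sequence), k = 21)
  # own k-mer returns own position (strand records the canonical form's
  # orientation on the contig, so either sign can appear here)
  km <- substr(g$sequence, 101, 121)
  h <- index_lookup(idx2, km)
  expect_true(any(h$pos == 101))
  # absent k-mer returns an empty table
  absent <- "TTTTTTTTTTTTTTTTTTTTT"
  if (!grepl(absent, g$sequence, fixed = TRUE)) {
    expect_equal(nrow(index_lookup(idx2, absent)), 0L)
  }
})

test_that("assign_read places exact and reverse-complement reads", {
  g <- generate_genome(5000, 0.5, seed = 55, circular = FALSE)
  idx <- build_index(c(c1 = g$sequence), k = 21)
  frag <- substr(g$sequence, 1001, 1400)
  pl <- assign_read(frag, idx, min_frac = 0.5)
  expect_equal(pl$contig_id, "c1")
  expect_equal(pl$strand, "+")
  expect_equal(pl$start, 1001L)
  expect_equal(pl$frac, 1)

  plrc <- assign_read(oracle_revcomp(frag), idx, min_frac = 0.5)
  expect_equal(plrc$strand, "-")
  expect_equal(plrc$start, 1001L)
  expect_equal(plrc$frac, 1)
})

test_that("a random read stays unassigned against an unrelated genome", {
  # chance 21-mer hit rate ~ L * 2 / 4^21 per position: effectively zero
  g <- generate_genome(100000, 0.5, seed = 56, circular = FALSE)
  idx <- build_index(c(c1 = g$sequence), k = 21)
  set.seed(57)
  for (i in 1:5) {
    rnd <- random_dna(400)
    pl <- assign_read(rnd, idx, min_frac = 0.3)
    expect_equal(nrow(pl), 0L)
  }
})

test_that("assign_read agrees with brute-force k-mer counting", {
  g1 <- generate_genome(2000, 0.5, seed = 58, circular = FALSE)
  g2 <- generate_genome(2000, 0.5, seed = 59, circular = FALSE)
  contigs <- c(g1$sequence, g2$sequence)
  idx <- build_index(contigs, k = 15)
  set.seed(60)
  for (i in 1:40) {
    # reads of varying relatedness: exact, mutated, half-chimeric, random
    kind <- sample(4, 1)
    src <- sample(2, 1)
    a <- sample(1500, 1)
    frag <- substr(contigs[src], a, a + 149)
    read <- switch(kind,
      frag,
      mutate_with_positions(frag, 0.05, seed = 600 + i)$sequence,
      paste0(substr(frag, 1, 75),
             substr(contigs[3 - src], a, a + 74)),
      random_dna(150))
    if (sample(2, 1) == 2) read <- oracle_revcomp(read)
    mine <- assign_read(read, idx, min_frac = 0.3)
    ref <- oracle_assign(read, contigs, 15, 0.3)
    if (is.null(ref)) {
      expect_equal(nrow(mine), 0L, info = paste("case", i))
    } else {
      expect_equal(nrow(mine), 1L, info = paste("case", i))
      expect_equal(match(mine$contig_id, c("c0001", "c0002")), ref$contig)
      expect_equal(mine$strand, ref$strand)
      expect_equal(mine$frac, ref$frac, tolerance = 1e-12)
    }
  }
})

test_that("every contig base is supported by min_kmer_count input k-mers", {
  g <- generate_genome(3000, 0.5, seed = 61, circular = FALSE)
  starts <- seq(1, 2801, by = 25)
  reads <- make_reads(substring(g$sequence, starts, starts + 199))
  asm <- assemble(reads, k = 31, min_kmer_count = 2)
  input_kmers <- table(unlist(lapply(reads$sequence, oracle_kmers, k = 31)))
  for (cs in asm$contigs$sequence) {
    ck <- oracle_kmers(cs, 31)
    expect_true(all(input_kmers[ck] >= 2))
  }
})
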