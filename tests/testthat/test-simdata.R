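test_that("generate_genome honours length, GC and determinism", {
  g <- generate_genome(10000, 0.47, seed = 1)
  expect_equal(nchar(g$sequence), 10000L)
  g2 <- generate_genome(10000, 0.47, seed = 1)
  expect_identical(g$sequence, g2$sequence)

  # observed GC within +-0.01 of target at n = 1e5 (binomial SE ~ 0.0016)
  g3 <- generate_genome(100000, 0.47, seed = 2)
  gc_obs <- nchar(gsub("[AT]", "", g3$sequence)) / 100000
  expect_lt(abs(gc_obs - 0.47), 0.01)

  expect_error(generate_genome(10000, 1.2, seed = 1), "gc")
  expect_error(generate_genome(100, 0.5, seed = 1))
})

test_that("shotgun simulation hits coverage, abundance and purity targets", {
  prof <- sim_profile()
  g <- generate_genome(50000, 0.5, seed = 3, id = "g1", circular = FALSE)

  # 20x coverage of a 50 kb genome -> ~1e6 bases (Poisson fragment count)
  sim <- simulate_shotgun(list(g), 1, prof, "A_long_single", seed = 4,
                          coverage = 20)
  expect_lt(abs(sum(nchar(sim$reads$sequence)) - 1e6), 0.02 * 1e6)
  expect_equal(nrow(sim$reads), nrow(sim$truth))
  expect_setequal(sim$reads$id, sim$truth$read_id)

  # abundance 0.8/0.2 recovered in truth labels within +-2 points
  g2 <- generate_genome(50000, 0.5, seed = 5, id = "g2", circular = FALSE)
  sim2 <- simulate_shotgun(list(g, g2), c(0.8, 0.2), prof, "B_short_paired",
                           seed = 6, coverage = 100)
  p_obs <- mean(sim2$truth$genome_id == "g1")
  expect_lt(abs(p_obs - 0.8), 0.02)

  # error rate 0 -> every read is an exact substring of its genome
  # (or its reverse complement); circular genomes checked on the doubled
  # sequence
  prof0 <- sim_profile(error_rate = 0)
  gc <- generate_genome(20000, 0.5, seed = 7, id = "gc")
  sim0 <- simulate_shotgun(list(gc), 1, prof0, "A_long_single", seed = 8,
                           coverage = 5)
  doubled <- paste0(gc$sequence, gc$sequence)
  ok <- vapply(sim0$reads$sequence, function(s) {
    grepl(s, doubled, fixed = TRUE) ||
      grepl(oracle_revcomp(s), doubled, fixed = TRUE)
  }, logical(1))
  expect_true(all(ok))
})

test_that("paired-end simulation emits symmetric, properly oriented mates", {
  prof <- sim_profile(error_rate = 0)
  g <- generate_genome(30000, 0.5, seed = 9, id = "g", circular = FALSE)
  sim <- simulate_shotgun(list(g), 1, prof, "B_short_paired", seed = 10,
                          coverage = 10)
  pairs <- split_pairs(sim$reads)
  expect_equal(pairs$r1$mate_id, pairs$r2$id)
  expect_equal(pairs$r2$mate_id, pairs$r1$id)
  expect_true(all(nchar(pairs$r1$sequence) == 251))
  # mates face each other: strands recorded in truth are opposite
  tr <- sim$truth
  s1 <- tr$strand[match(pairs$r1$id, tr$read_id)]
  s2 <- tr$strand[match(pairs$r2$id, tr$read_id)]
  expect_true(all(s1 != s2))
  # truth intervals reproduce read sequences exactly at error rate 0
  for (i in sample(nrow(pairs$r1), 20)) {
    row <- tr[tr$read_id == pairs$r1$id[i], ]
    frag <- substr(g$sequence, row$start, row$end)
    if (row$strand == "-") frag <- oracle_revcomp(frag)
    expect_identical(pairs$r1$sequence[i], frag)
  }
})

test_that("WGA chimera rate is honoured at its extremes and in between", {
  g <- generate_genome(50000, 0.5, seed = 11, id = "g")
  doubled <- paste0(g$sequence, g$sequence)

  # rate 0: every read is an exact (possibly reverse-complemented) substring
  p0 <- sim_profile(error_rate = 0, wga_chimera_rate = 0, coverage_wga = 2)
  w0 <- simulate_wga(g, p0, seed = 12)
  ok <- vapply(w0$reads$sequence, function(s) {
    grepl(s, doubled, fixed = TRUE) ||
      grepl(oracle_revcomp(s), doubled, fixed = TRUE)
  }, logical(1))
  expect_true(all(ok))
  expect_false(any(w0$truth$is_chimera))

  # rate 1: every truth row carries two intervals
  p1 <- sim_profile(error_rate = 0, wga_chimera_rate = 1, coverage_wga = 2)
  w1 <- simulate_wga(g, p1, seed = 13)
  expect_true(all(w1$truth$is_chimera))
  expect_true(all(!is.na(w1$truth$start2)))

  # rate 0.3 at n ~ 1e4: chimeric fraction within +-1.5 points
  p3 <- sim_profile(wga_chimera_rate = 0.3, coverage_wga = 80)
  w3 <- simulate_wga(g, p3, seed = 14)
  expect_gt(nrow(w3$reads), 5000)
  expect_lt(abs(mean(w3$truth$is_chimera) - 0.3), 0.015)
})

test_that("simulation output is byte-identical under a fixed seed", {
  prof <- sim_profile()
  sim1 <- simulate_coculture(prof, seed = 42, genome_length = 20000)
  sim2 <- simulate_coculture(prof, seed = 42, genome_length = 20000)
  expect_identical(sim1$bait$reads, sim2$bait$reads)
  expect_identical(sim1$ds_b$reads, sim2$ds_b$reads)
  expect_identical(sim1$truth, sim2$truth)
  # and FASTQ serialisation is too
  p1 <- withr::local_tempfile(fileext = ".fastq")
  p2 <- withr::local_tempfile(fileext = ".fastq")
  write_fastq(sim1$bait$reads, p1)
  write_fastq(sim2$bait$reads, p2)
  expect_identical(readLines(p1), readLines(p2))

  # truth partitions the read set: exactly one entry per read
  all_ids <- c(sim1$bait$reads$id, sim1$ds_a$reads$id, sim1$ds_b$reads$id)
  expect_equal(sort(sim1$truth$read_id), sort(all_ids))
  expect_false(any(duplicated(sim1$truth$read_id)))
})
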