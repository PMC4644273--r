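# small fixture: an assembly object built by hand
toy_assembly <- function(placements) {
  contigs <- data.frame(id = unique(c(placements$contig_id, "c1", "c2")),
                        sequence = "ACGT", mean_coverage = 1,
                        stringsAsFactors = FALSE)
  structure(list(contigs = contigs, placements = placements),
            class = "Assembly")
}

pl_row <- function(read_id, contig_id, start = 1L, strand = "+", frac = 1) {
  data.frame(read_id = read_id, contig_id = contig_id, start = start,
             strand = strand, frac = frac, stringsAsFactors = FALSE)
}

test_that("bait-supported contig selection applies the inclusive threshold", {
  asm <- toy_assembly(empty_pl())
  baits5 <- pl_row(sprintf("w%d", 1:5), "c1")
  expect_setequal(pick_bait_contigs(asm, baits5, 1), "c1")
  expect_length(pick_bait_contigs(asm, baits5, 6), 0)
  baits22 <- rbind(pl_row(c("w1", "w2"), "c1"), pl_row(c("w3", "w4"), "c2"))
  expect_setequal(pick_bait_contigs(asm, baits22, 2), c("c1", "c2"))
  # monotone: a higher threshold never grows the selection
  for (m in 1:4) {
    expect_true(all(pick_bait_contigs(asm, baits22, m + 1) %in%
                      pick_bait_contigs(asm, baits22, m)))
  }
})

test_that("read recovery follows placements and pair semantics", {
  asm <- toy_assembly(rbind(pl_row("r1", "c1"), pl_row("r2", "c2"),
                            pl_row("r3", "c1")))
  expect_setequal(recover_reads(asm, "c1", c("r1", "r2", "r3")),
                  c("r1", "r3"))
  expect_length(recover_reads(asm, character(0), c("r1", "r2")), 0)
  # one placed mate pulls in the unplaced one
  asm2 <- toy_assembly(pl_row("p1/1", "c1"))
  expect_setequal(recover_reads(asm2, "c1", c("p1/1", "p1/2")),
                  c("p1/1", "p1/2"))
  # but not when the mate was lost in QC (absent from the universe)
  expect_setequal(recover_reads(asm2, "c1", "p1/1"), "p1/1")
})

test_that("coverage subsampling is atomic over pairs and deterministic", {
  set.seed(20)
  n <- 1000
  ids <- as.vector(rbind(sprintf("p%04d/1", 1:n), sprintf("p%04d/2", 1:n)))
  reads <- make_reads(replicate(2 * n, random_dna(500)), ids = ids)

  # target above availability -> unchanged
  expect_identical(subsample_to_coverage(reads, 1e5, 100, seed = 1), reads)

  # 1e6 bases available, target 5e5 -> retained within +-2%
  sub <- subsample_to_coverage(reads, 1e5, 5, seed = 2)
  expect_lt(abs(sum(nchar(sub$sequence)) - 5e5), 0.02 * 5e5)
  # pairs stay together
  expect_true(all(table(sub("/[12]$", "", sub$id)) == 2L))
  # determinism
  sub2 <- subsample_to_coverage(reads, 1e5, 5, seed = 2)
  expect_identical(sub, sub2)
})

test_that("evaluation implements the stated precision/recall conventions", {
  truth <- data.frame(
    read_id = c(sprintf("A%03d", 1:10), sprintf("B%03d", 1:10)),
    genome_id = rep(c("target", "contaminant"), each = 10),
    stringsAsFactors = FALSE)
  fake_result <- function(picked) {
    structure(list(step3_picked_ids = picked,
                   step5_picked_pair_ids = character(0),
                   step5_picked_single_ids = character(0),
                   final_assembly = new_asm(),
                   universe_a_ids = truth$read_id,
                   universe_b_ids = character(0)),
              class = "PickResult")
  }
  new_asm <- function() structure(
    list(contigs = data.frame(id = "c1", sequence = "ACGTACGT",
                              mean_coverage = 1, stringsAsFactors = FALSE),
         placements = NULL), class = "Assembly")

  # picks exactly the target reads -> precision 1, recall 1
  ev <- evaluate_picking(fake_result(sprintf("A%03d", 1:10)), truth)
  expect_equal(ev$precision, 1)
  expect_equal(ev$recall, 1)
  # half the target reads, no contaminants -> precision 1, recall 0.5
  ev2 <- evaluate_picking(fake_result(sprintf("A%03d", 1:5)), truth)
  expect_equal(ev2$precision, 1)
  expect_equal(ev2$recall, 0.5)
  # empty picks -> precision undefined, recall 0
  ev3 <- evaluate_picking(fake_result(character(0)), truth)
  expect_true(is.na(ev3$precision))
  expect_equal(ev3$recall, 0)
  # picked id missing from the truth table is an error
  expect_error(evaluate_picking(fake_result("Z999"), truth), "truth")
})

test_that("pure-culture degenerate run recovers every placed read", {
  # no contaminant: baits and shotgun reads from the same genome
  prof <- sim_profile(wga_chimera_rate = 0, coverage_a = 20,
                      coverage_b = 60, coverage_wga = 5)
  set.seed(30)
  g <- generate_genome(30000, 0.47, id = "target")
  bait <- simulate_wga(g, prof, seed = 31)
  ds_a <- simulate_shotgun(list(g), 1, prof, "A_long_single", seed = 32)
  ds_b <- simulate_shotgun(list(g), 1, prof, "B_short_paired", seed = 33)
  cfg <- run_config(seed = 34, genome_size_estimate = 30000)
  res <- suppressMessages(
    run_pipeline(bait$reads, ds_a$reads, split_pairs(ds_b$reads), cfg))
  truth <- rbind(bait$truth, ds_a$truth, ds_b$truth)
  ev <- evaluate_picking(res, truth, "target", g)
  expect_equal(ev$precision, 1)
  expect_gt(ev$recall, 0.98)
  expect_gt(ev$target_completeness, 0.98)
})

test_that("bait choice drives the picking: contaminant baits pick the
          contaminant", {
  prof <- sim_profile(coverage_a = 30, coverage_b = 60, coverage_wga = 8)
  sim <- simulate_coculture(prof, seed = 35, genome_length = 30000)
  cfg <- run_config(seed = 35, genome_size_estimate = 30000)
  # swap the bait library to the contaminant's WGA reads
  bait_x <- simulate_wga(sim$contaminant, prof, seed = 36, id_prefix = "X")
  truth <- rbind(bait_x$truth, sim$ds_a$truth, sim$ds_b$truth)
  res <- suppressMessages(
    run_pipeline(bait_x$reads, sim$ds_a$reads, split_pairs(sim$ds_b$reads),
                 cfg))
  picked <- picked_read_ids(res)
  origin <- truth$genome_id[match(picked, truth$read_id)]
  expect_gt(mean(origin == "contaminant"), 0.95)
})

test_that("pick sets are conserved, disjoint across platforms, and
          deterministic", {
  prof <- sim_profile(coverage_a = 25, coverage_b = 60, coverage_wga = 6)
  sim <- simulate_coculture(prof, seed = 37, genome_length = 25000)
  cfg <- run_config(seed = 37, genome_size_estimate = 25000)
  run <- function() suppressMessages(
    run_pipeline(sim$bait$reads, sim$ds_a$reads, split_pairs(sim$ds_b$reads),
                 cfg))
  res <- run()
  expect_true(all(res$step3_picked_ids %in% sim$ds_a$reads$id))
  expect_true(all(paste0(res$step5_picked_pair_ids, "/1") %in%
                    sim$ds_b$reads$id))
  expect_length(intersect(res$step3_picked_ids,
                          c(paste0(res$step5_picked_pair_ids, "/1"),
                            res$step5_picked_single_ids)), 0)
  # counts mirror the pick sets
  expect_equal(res$counts$step3$n_reads, length(res$step3_picked_ids))
  res2 <- run()
  expect_identical(res$step3_picked_ids, res2$step3_picked_ids)
  expect_identical(res$final_assembly$contigs$sequence,
                   res2$final_assembly$contigs$sequence)
})

test_that("shared sequence between organisms degrades precision", {
  prof <- sim_profile(coverage_a = 25, coverage_b = 60, coverage_wga = 6)
  cfg <- function(s) run_config(seed = s, genome_size_estimate = 25000)
  prec <- function(shared, seed) {
    sim <- simulate_coculture(prof, seed = seed, genome_length = 25000,
                              shared_frac = shared)
    res <- suppressMessages(run_pipeline(
      sim$bait$reads, sim$ds_a$reads, split_pairs(sim$ds_b$reads),
      cfg(seed)))
    evaluate_picking(res, sim$truth, "target")$precision
  }
  p0 <- mean(c(prec(0, 38), prec(0, 39)))
  p10 <- mean(c(prec(0.10, 38), prec(0.10, 39)))
  expect_lte(p10, p0 + 0.005)
  expect_lt(p10, 1)  # contaminant reads from the shared region get picked
})

test_that("scaffold report ranks junctions by spanning-pair support", {
  # a genome split at a gap into two contigs, with pairs spanning the gap
  g <- generate_genome(6000, 0.5, seed = 40, circular = FALSE)
  c1 <- substr(g$sequence, 1, 3000)
  c2 <- substr(g$sequence, 3101, 6000)
  contigs <- data.frame(id = c("c1", "c2"),
                        sequence = c(c1, c2), mean_coverage = 10,
                        stringsAsFactors = FALSE)
  idx <- build_index(contigs, k = 21)
  # mate pairs spanning the gap: r1 near the end of c1, r2 (rc) inside c2
  spans <- lapply(1:8, function(i) {
    a <- 2800 + i * 10
    b <- 3150 + i * 10
    make_reads(c(substr(g$sequence, a, a + 99),
                 oracle_revcomp(substr(g$sequence, b, b + 99))),
               ids = sprintf("sp%02d/%d", i, 1:2))
  })
  intra <- make_reads(c(substr(c1, 100, 199), oracle_revcomp(
    substr(c1, 500, 599))), ids = c("in01/1", "in01/2"))
  reads <- do.call(rbind, c(spans, list(intra)))
  pl <- assign_read(reads, idx, min_frac = 0.5)
  asm <- structure(list(contigs = contigs, placements = pl),
                   class = "Assembly")
  rep <- scaffold_report(asm)
  expect_equal(nrow(rep), 1L)
  expect_equal(rep$contig_a, "c1")
  expect_equal(rep$contig_b, "c2")
  expect_equal(rep$n_pairs, 8L)

  # single-contig assembly and intra-contig pairs produce empty reports
  asm_intra <- structure(list(contigs = contigs,
                              placements = assign_read(intra, idx, 0.5)),
                         class = "Assembly")
  expect_equal(nrow(scaffold_report(asm_intra)), 0L)
  expect_equal(nrow(scaffold_report(structure(
    list(contigs = contigs[1, ], placements = empty_pl()), class = "Assembly"))),
    0L)
})
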