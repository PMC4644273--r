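#' Simulation profile for co-culture sequencing
#'
#' Parameters of the synthetic read generator: read-length distributions for
#' the long single-end platform (A) and the short paired-end platform (B),
#' insert sizes, the substitution error rate, the quality model, coverage
#' targets, the abundance ratio of the two organisms, and the whole-genome
#' amplification (WGA) artifact model (chimera rate and lognormal window
#' amplification bias).
#'
#' @param ... named overrides of default keys.
#' @return a named list of class `sim_profile`.
#' @details Defaults: platform A read length ~ Normal(400, 80) bp; platform B
#' fixed 251 bp with insert ~ Normal(500, 50); substitution error rate 0.005;
#' qualities ~ Normal(37 - 0.02 x position, 2) clamped between 2 and 40;
#' coverage
#' 40x (A), 200x (B), 10x (WGA baits) against the co-culture, split by the
#' abundance vector (0.5, 0.5) so each organism sees 20x/100x; WGA chimera
#' rate 0.1; WGA bias sigma 0.8 over 5 kb windows.
#' @export
sim_profile <- function(...) {
  p <- list(
    read_len_a_mean = 400, read_len_a_sd = 80, read_len_a_min = 80,
    read_len_b = 251L,
    insert_mean = 500, insert_sd = 50,
    error_rate = 0.005,
    qual_mean = 37, qual_decay = 0.02, qual_sd = 2,
    coverage_a = 40, coverage_b = 200, coverage_wga = 10,
    abundance = c(0.5, 0.5),
    wga_chimera_rate = 0.1,
    wga_bias_sigma = 0.8,
    wga_window = 5000L
  )
  over <- list(...)
  if (length(over)) {
    unknown <- setdiff(names(over), names(p))
    if (length(unknown)) stop("unknown profile keys: ",
                              paste(unknown, collapse = ", "))
    p[names(over)] <- over
  }
  stopifnot(p$error_rate >= 0, p$error_rate <= 1,
            p$wga_chimera_rate >= 0, p$wga_chimera_rate <= 1,
            p$coverage_a > 0, p$coverage_b > 0, p$coverage_wga > 0,
            all(p$abundance > 0), abs(sum(p$abundance) - 1) < 1e-8)
  structure(p, class = c("sim_profile", "list"))
}

#' Generate a random genome
#'
#' I.i.d. bases with the requested G+C fraction.
#'
#' @param length genome length in bp (>= 1000).
#' @param gc G+C fraction, strictly between 0 and 1.
#' @param seed random seed.
#' @param id sequence identifier.
#' @param circular logical; circular genomes allow fragments to wrap the
#'   origin during simulation.
#' @return a `SynGenome`: list with `id`, `sequence`, `circular`.
#' @export
generate_genome <- function(length, gc, seed = NULL, id = "g1",
                            circular = TRUE) {
  stopifnot(length >= 1000)
  if (gc <= 0 || gc >= 1) stop("gc must be strictly between 0 and 1")
  with_seed(seed, {
    bases <- sample(c("A", "C", "G", "T"), length, replace = TRUE,
                    prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
    structure(list(id = id, sequence = paste(bases, collapse = ""),
                   circular = circular),
              class = "SynGenome")
  })
}

# Extract substrings from a (possibly circular) genome.  starts are 1-based;
# intervals may run past L for circular genomes (positions taken mod L).
extract_frags <- function(genome, starts, lens) {
  L <- nchar(genome$sequence)
  if (any(lens > L)) stop("requested read length exceeds genome length")
  src <- if (genome$circular) paste0(genome$sequence, genome$sequence)
         else genome$sequence
  if (!genome$circular) starts <- pmin(starts, L - lens + 1L)
  substring(src, starts, starts + lens - 1L)
}

finish_reads <- function(ids, seqs, strands, quals, platform, mate_ids = NA) {
  seqs[strands == "-"] <- revcomp(seqs[strands == "-"])
  data.frame(id = ids, platform = platform, sequence = seqs,
             quality = quals, mate_id = mate_ids, stringsAsFactors = FALSE)
}

#' Simulate direct-shotgun reads from a co-culture
#'
#' Draws error-bearing shotgun reads from a set of genomes with the given
#' abundance ratio.  Per-genome expected coverage is the total coverage times
#' the genome's abundance.  Platform `"B_short_paired"` emits proper mate
#' pairs (forward / reverse-complement, insert size from the profile);
#' platform `"A_long_single"` emits single-end reads with Normal-distributed
#' lengths.  Every read carries a truth label in the returned sidecar.
#'
#' @param genomes list of `SynGenome`.
#' @param abundances numeric vector summing to 1, one entry per genome.
#' @param profile a [sim_profile()].
#' @param platform `"A_long_single"` or `"B_short_paired"`.
#' @param seed random seed.
#' @param coverage total coverage; defaults to the profile's per-platform
#'   coverage target.
#' @param id_prefix prefix for read identifiers.
#' @return a list with `reads` (read data frame) and `truth` (truth sidecar
#'   data frame).
#' @export
simulate_shotgun <- function(genomes, abundances, profile = sim_profile(),
                             platform = c("A_long_single", "B_short_paired"),
                             seed = NULL, coverage = NULL, id_prefix = NULL) {
  platform <- match.arg(platform)
  if (inherits(genomes, "SynGenome")) genomes <- list(genomes)
  stopifnot(length(genomes) == length(abundances),
            abs(sum(abundances) - 1) < 1e-8)
  if (is.null(coverage)) {
    coverage <- if (platform == "A_long_single") profile$coverage_a
                else profile$coverage_b
  }
  if (is.null(id_prefix)) {
    id_prefix <- if (platform == "A_long_single") "A" else "B"
  }
  with_seed(seed, {
    reads <- list(); truths <- list()
    counter <- 0L
    for (gi in seq_along(genomes)) {
      g <- genomes[[gi]]
      L <- nchar(g$sequence)
      bases_target <- coverage * abundances[gi] * L
      if (platform == "A_long_single") {
        n <- stats::rpois(1, bases_target / profile$read_len_a_mean)
        if (n == 0) next
        lens <- pmax(profile$read_len_a_min,
                     pmin(L, round(stats::rnorm(n, profile$read_len_a_mean,
                                                profile$read_len_a_sd))))
        starts <- sample.int(L, n, replace = TRUE)
        strands <- sample(c("+", "-"), n, replace = TRUE)
        seqs <- extract_frags(g, starts, lens)
        ids <- sprintf("%s%07d", id_prefix, counter + seq_len(n))
        counter <- counter + n
        quals <- cpp_phred_strings(lens, profile$qual_mean,
                                   profile$qual_decay, profile$qual_sd)
        reads[[gi]] <- finish_reads(ids, seqs, strands, quals, platform)
        truths[[gi]] <- data.frame(
          read_id = ids, genome_id = g$id, start = starts,
          end = starts + lens - 1L, strand = strands, is_chimera = FALSE,
          start2 = NA_integer_, end2 = NA_integer_, strand2 = NA_character_,
          stringsAsFactors = FALSE)
      } else {
        rl <- profile$read_len_b
        if (rl > L) stop("requested read length exceeds genome length")
        n <- stats::rpois(1, bases_target / (2 * rl))
        if (n == 0) next
        frag <- pmax(rl, pmin(L, round(stats::rnorm(n, profile$insert_mean,
                                                    profile$insert_sd))))
        fs <- sample.int(L, n, replace = TRUE)
        fe <- fs + frag - 1L
        fstrand <- sample(c("+", "-"), n, replace = TRUE)
        pair <- sprintf("%s%07d", id_prefix, counter + seq_len(n))
        counter <- counter + n
        fwd <- fstrand == "+"
        r1_start <- ifelse(fwd, fs, fe - rl + 1L)
        r2_start <- ifelse(fwd, fe - rl + 1L, fs)
        r1_strand <- ifelse(fwd, "+", "-")
        r2_strand <- ifelse(fwd, "-", "+")
        r1_seq <- extract_frags(g, r1_start, rep(rl, n))
        r2_seq <- extract_frags(g, r2_start, rep(rl, n))
        q <- cpp_phred_strings(rep(rl, 2L * n), profile$qual_mean,
                               profile$qual_decay, profile$qual_sd)
        r1 <- finish_reads(paste0(pair, "/1"), r1_seq, r1_strand,
                           q[seq_len(n)], platform, paste0(pair, "/2"))
        r2 <- finish_reads(paste0(pair, "/2"), r2_seq, r2_strand,
                           q[n + seq_len(n)], platform, paste0(pair, "/1"))
        # interleave mates so pairs stay adjacent
        ord <- as.vector(rbind(seq_len(n), n + seq_len(n)))
        both <- rbind(r1, r2)[ord, ]
        rownames(both) <- NULL
        reads[[gi]] <- both
        tr <- data.frame(
          read_id = c(paste0(pair, "/1"), paste0(pair, "/2")),
          genome_id = g$id,
          start = c(r1_start, r2_start),
          end = c(r1_start + rl - 1L, r2_start + rl - 1L),
          strand = c(r1_strand, r2_strand), is_chimera = FALSE,
          start2 = NA_integer_, end2 = NA_integer_,
          strand2 = NA_character_, stringsAsFactors = FALSE)
        truths[[gi]] <- tr[order(match(tr$read_id, both$id)), ]
      }
    }
    reads <- do.call(rbind, reads)
    truth <- do.call(rbind, truths)
    if (is.null(reads)) {
      return(list(reads = empty_reads(), truth = NULL))
    }
    rownames(reads) <- rownames(truth) <- NULL
    reads$sequence <- cpp_add_substitutions(reads$sequence,
                                            profile$error_rate)
    list(reads = reads, truth = truth)
  })
}

# biased locus sampler for the WGA model: genome tiled into fixed windows,
# each weighted by a lognormal amplification factor
wga_sample_starts <- function(n, L, window, sigma) {
  nwin <- max(1L, ceiling(L / window))
  w_start <- (seq_len(nwin) - 1L) * window + 1L
  w_len <- pmin(window, L - w_start + 1L)
  weight <- stats::rlnorm(nwin, 0, sigma) * w_len
  win <- sample.int(nwin, n, replace = TRUE, prob = weight)
  w_start[win] + floor(stats::runif(n) * w_len[win])
}

#' Simulate whole-genome-amplification bait reads
#'
#' Emulates a WGA (multiple-displacement amplification) library from a pure
#' culture: long single-end reads with uneven, lognormally biased coverage
#' and a fraction of chimeric reads, each joining two independently drawn
#' loci (uniform junction point along the read, either strand).
#'
#' @param genome a `SynGenome`.
#' @param profile a [sim_profile()]; uses `coverage_wga`, `wga_chimera_rate`,
#'   `wga_bias_sigma` and `wga_window`.
#' @param seed random seed.
#' @param id_prefix prefix for read identifiers.
#' @return a list with `reads` and `truth`; chimeric truth rows carry two
#'   intervals (`start`/`end`/`strand` and `start2`/`end2`/`strand2`).
#' @export
simulate_wga <- function(genome, profile = sim_profile(), seed = NULL,
                         id_prefix = "W") {
  stopifnot(inherits(genome, "SynGenome"), nchar(genome$sequence) > 0)
  with_seed(seed, {
    L <- nchar(genome$sequence)
    n <- stats::rpois(1, profile$coverage_wga * L / profile$read_len_a_mean)
    if (n == 0) {
      return(list(reads = empty_reads(), truth = NULL))
    }
    lens <- pmax(profile$read_len_a_min,
                 pmin(L, round(stats::rnorm(n, profile$read_len_a_mean,
                                            profile$read_len_a_sd))))
    chim <- stats::runif(n) < profile$wga_chimera_rate
    ids <- sprintf("%s%07d", id_prefix, seq_len(n))

    s1 <- wga_sample_starts(n, L, profile$wga_window, profile$wga_bias_sigma)
    st1 <- sample(c("+", "-"), n, replace = TRUE)
    # junction point uniform in [1, len-1] for chimeric reads
    j <- ifelse(chim, 1L + floor(stats::runif(n) * (lens - 1L)), lens)
    l1 <- as.integer(j)
    l2 <- as.integer(lens - j)
    s2 <- wga_sample_starts(n, L, profile$wga_window, profile$wga_bias_sigma)
    st2 <- sample(c("+", "-"), n, replace = TRUE)

    seg1 <- extract_frags(genome, s1, l1)
    seg1[st1 == "-"] <- revcomp(seg1[st1 == "-"])
    seqs <- seg1
    if (any(chim)) {
      seg2 <- extract_frags(genome, s2[chim], l2[chim])
      flip <- st2[chim] == "-"
      seg2[flip] <- revcomp(seg2[flip])
      seqs[chim] <- paste0(seg1[chim], seg2)
    }
    quals <- cpp_phred_strings(lens, profile$qual_mean, profile$qual_decay,
                               profile$qual_sd)
    reads <- data.frame(id = ids, platform = "A_long_single",
                        sequence = cpp_add_substitutions(seqs,
                                                         profile$error_rate),
                        quality = quals, mate_id = NA_character_,
                        stringsAsFactors = FALSE)
    truth <- data.frame(
      read_id = ids, genome_id = genome$id,
      start = s1, end = s1 + l1 - 1L, strand = st1,
      is_chimera = chim,
      start2 = ifelse(chim, s2, NA_integer_),
      end2 = ifelse(chim, s2 + l2 - 1L, NA_integer_),
      strand2 = ifelse(chim, st2, NA_character_),
      stringsAsFactors = FALSE)
    list(reads = reads, truth = truth)
  })
}

#' Simulate a complete two-organism co-culture sequencing experiment
#'
#' Builds a target and a contaminant genome, direct-shotgun libraries on both
#' platforms from the co-culture, and a WGA bait library from the target's
#' pure culture.  This is the standard scenario the package's recovery tests
#' run on.
#'
#' @param profile a [sim_profile()].
#' @param seed random seed.
#' @param genome_length length of each genome, bp.
#' @param gc G+C fraction of both genomes.
#' @param shared_frac fraction of the target genome copied into the
#'   contaminant (0 = fully distinct organisms); models shared/homologous
#'   sequence, the method's known failure mode.
#' @return list with `target`, `contaminant` (`SynGenome`), `bait`, `ds_a`,
#'   `ds_b` (each a `reads` + `truth` list), and `truth` (combined sidecar).
#' @export
simulate_coculture <- function(profile = sim_profile(), seed = 1,
                               genome_length = 1e5, gc = 0.47,
                               shared_frac = 0) {
  with_seed(seed, {
    target <- generate_genome(genome_length, gc, id = "target")
    contaminant <- generate_genome(genome_length, gc, id = "contaminant")
    if (shared_frac > 0) {
      sl <- floor(shared_frac * genome_length)
      shared <- substr(target$sequence, 1L, sl)
      contaminant$sequence <- paste0(
        shared, substr(contaminant$sequence, sl + 1L, genome_length))
    }
    genomes <- list(target, contaminant)
    bait <- simulate_wga(target, profile)
    ds_a <- simulate_shotgun(genomes, profile$abundance, profile,
                             "A_long_single")
    ds_b <- simulate_shotgun(genomes, profile$abundance, profile,
                             "B_short_paired")
    truth <- rbind(bait$truth, ds_a$truth, ds_b$truth)
    rownames(truth) <- NULL
    list(target = target, contaminant = contaminant, bait = bait,
         ds_a = ds_a, ds_b = ds_b, truth = truth, profile = profile)
  })
}

#' Write / read a truth sidecar TSV
#'
#' @param truth truth data frame as produced by the simulators.
#' @param path TSV path.
#' @return `path` invisibly, or the truth data frame.
#' @export
write_truth <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}

#' Split an interleaved paired read table into mate data frames
#'
#' @param reads read data frame with ids ending in `/1` and `/2`.
#' @return list with elements `r1` and `r2`, aligned by pair.
#' @export
split_pairs <- function(reads) {
  r1 <- reads[endsWith(reads$id, "/1"), , drop = FALSE]
  r2 <- reads[endsWith(reads$id, "/2"), , drop = FALSE]
  stopifnot(nrow(r1) == nrow(r2),
            identical(sub("/1$", "", r1$id), sub("/2$", "", r2$id)))
  rownames(r1) <- rownames(r2) <- NULL
  list(r1 = r1, r2 = r2)
}
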