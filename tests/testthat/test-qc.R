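test_that("trimming keeps, cuts and discards reads per the window rule", {
  # all above threshold -> unchanged
  r <- make_reads(random_dna(50, seed = 1), quals = phred_string(rep(30, 50)))
  out <- trim_read(r, 20, 0.1, 20)
  expect_equal(out$sequence, r$sequence)

  # all below threshold -> discarded
  r2 <- make_reads(random_dna(50, seed = 2), quals = phred_string(rep(2, 50)))
  expect_null(trim_read(r2, 20, 0.1, 20))

  # 100 bp read, 60 bases Q35 then 40 bases Q5: kept length fixed by the
  # brute-force window walk (window 10; first failing window starts at 57)
  q <- c(rep(35, 60), rep(5, 40))
  r3 <- make_reads(random_dna(100, seed = 3), quals = phred_string(q))
  out3 <- trim_read(r3, 20, 0.1, 20)
  ref <- oracle_trim(q, 20, 0.1)
  expect_equal(nchar(out3$sequence), unname(ref["end"] - ref["start"] + 1L))
  expect_true(nchar(out3$sequence) >= 55 && nchar(out3$sequence) <= 70)
  expect_equal(out3$sequence,
               substr(r3$sequence, ref["start"], ref["end"]))
})

test_that("trimming matches the brute-force window walk on random reads", {
  set.seed(77)
  for (i in 1:200) {
    L <- sample(25:300, 1)
    q <- pmin(40, pmax(2, round(rnorm(L, mean = runif(1, 5, 38), sd = 8))))
    r <- make_reads(random_dna(L), quals = phred_string(q))
    qt <- sample(c(15, 20, 25), 1)
    wf <- sample(c(0.05, 0.1, 0.2), 1)
    out <- trim_read(r, qt, wf, 1)
    ref <- oracle_trim(q, qt, wf)
    if (is.null(ref)) {
      expect_null(out)
    } else {
      expect_equal(out$sequence,
                   substr(r$sequence, ref["start"], ref["end"]),
                   info = paste("case", i))
    }
  }
})

test_that("trimmed reads are substrings and never lengthen with stricter q
          on decaying quality profiles", {
  # the monotonicity guarantee applies to non-increasing quality profiles
  # (the realistic shape); with adversarial oscillating qualities a higher
  # threshold can skip a noisy 5' block and legitimately keep more
  set.seed(78)
  for (i in 1:50) {
    L <- sample(40:250, 1)
    q0 <- runif(1, 20, 40)
    slope <- runif(1, 0.02, 0.25)
    q <- pmin(40, pmax(2, round(q0 - slope * (seq_len(L) - 1))))
    r <- make_reads(random_dna(L), quals = phred_string(q))
    prev_len <- Inf
    for (qt in c(10, 15, 20, 25, 30)) {
      out <- trim_read(r, qt, 0.1, 1)
      len <- if (is.null(out)) 0L else nchar(out$sequence)
      expect_lte(len, prev_len)
      prev_len <- len
      if (!is.null(out)) {
        expect_true(grepl(out$sequence, r$sequence, fixed = TRUE))
      }
    }
  }
})

test_that("pair trimming partitions reads into pairs, singles, discards", {
  hi <- phred_string(rep(30, 50))
  lo <- phred_string(rep(2, 50))
  s <- random_dna(50, seed = 5)

  both <- trim_pairs(make_reads(s, hi, ids = "p1/1"),
                     make_reads(s, hi, ids = "p1/2"))
  expect_equal(nrow(both$kept_r1), 1L)
  expect_equal(nrow(both$kept_singles), 0L)
  expect_equal(both$discarded_count, 0L)

  one <- trim_pairs(make_reads(s, hi, ids = "p1/1"),
                    make_reads(s, lo, ids = "p1/2"))
  expect_equal(nrow(one$kept_r1), 0L)
  expect_equal(nrow(one$kept_singles), 1L)
  expect_equal(one$kept_singles$id, "p1/1")
  expect_equal(one$discarded_count, 1L)

  none <- trim_pairs(make_reads(s, lo, ids = "p1/1"),
                     make_reads(s, lo, ids = "p1/2"))
  expect_equal(nrow(none$kept_r1), 0L)
  expect_equal(none$discarded_count, 2L)

  expect_error(trim_pairs(make_reads(c(s, s)), make_reads(s)), "differ")

  # count partition on a random batch: 2*pairs + singles + discarded = input
  set.seed(6)
  n <- 200
  mkq <- function() phred_string(pmin(40, pmax(2, round(rnorm(60, 22, 10)))))
  r1 <- make_reads(replicate(n, random_dna(60)),
                   quals = replicate(n, mkq()),
                   ids = sprintf("p%03d/1", 1:n))
  r2 <- make_reads(replicate(n, random_dna(60)),
                   quals = replicate(n, mkq()),
                   ids = sprintf("p%03d/2", 1:n))
  tr <- trim_pairs(r1, r2)
  expect_equal(2L * nrow(tr$kept_r1) + nrow(tr$kept_singles) +
                 tr$discarded_count, 2L * n)
})
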