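# diffpickr

Bait-guided **differential read picking**: recovering a target organism's
genome from co-culture shotgun sequencing, for microbiologists working
with organisms that cannot be grown to sequencing-grade biomass in pure
culture (dehalorespiring *Dehalococcoides*-like anaerobes being the
motivating case).

## The method

Two libraries exist for such an organism: a whole-genome-amplification
(WGA) library from the scarce pure culture — chimera-rich and unevenly
amplified, unusable for assembly on its own — and clean direct-shotgun
(DS) libraries from a co-culture with a helper organism, in which the
reads of the two genomes are mixed.  Differential read picking uses the
WGA reads only as *bait*:

1. assemble the long single-end DS reads into contigs;
2. map the WGA bait reads to those contigs;
3. recover the DS reads on bait-supported contigs (they are taken to
   originate from the target);
4. co-assemble them with the trimmed, coverage-subsampled short
   paired-end DS reads;
5. pick the short reads that co-assembled with the picked long reads;
6. re-assemble all picked reads into the final assembly.

A chimeric bait still votes for the right contig over the part of its
length that maps, so the WGA artifacts that break assembly do not hurt
binning.  On truth-labelled synthetic co-cultures the package evaluates
the result as picking precision/recall and, by exact canonical 31-mer
comparison, final-assembly target completeness and contaminant fraction.

The package also ships the downstream characterisation tools such a
project needs: genome statistics from GenBank flat files (size, G+C %,
merged-union coding bp, feature counts), ANIb average nucleotide identity
(1020 bp fragments, 30% identity / 70% coverage retention, mean of best
hits), and CRISPR direct-repeat/spacer array detection with repeat
consensus and 1-based array coordinates.

## Worked example

Simulate the standard two-organism scenario (two 100 kb genomes, target
and contaminant at equal abundance; platform A long reads at 20× per
organism, platform B 251 bp pairs at 100×, WGA baits at 10× with 10%
chimeras), run the pipeline, and score it against the truth labels:

```r
library(diffpickr)

sim <- simulate_coculture(sim_profile(), seed = 7)
res <- run_pipeline(sim$bait$reads, sim$ds_a$reads,
                    split_pairs(sim$ds_b$reads), run_config(seed = 7))
#> [input_bait] WGA bait reads: 2,526 reads (1,009,940 bp)
#> [input_a] platform A DS reads: 10,074 reads (4,033,810 bp)
#> [input_b] platform B DS reads: 79,532 reads (19,962,532 bp)
#> [step1] assembled 2 contigs (200,060 bp)
#> [step2] 2526/2526 bait reads mapped
#> [step3] picked platform A reads: 5,018 reads (2,007,513 bp)
#> [step4_b_pool] trimmed+subsampled platform B reads: 39,840 reads (9,999,840 bp)
#> [step4] co-assembly: 2 contigs (200,060 bp)
#> [step5] picked platform B reads: 19,966 reads (5,011,466 bp)
#> [step6] final assembly: 1 contigs (100,030 bp)

evaluate_picking(res, sim$truth, "target", sim$target, sim$contaminant)
#> PickEval: precision 1.0000, recall 0.9994, completeness 1.0000, contaminant 0
```

Reading the log: step 1 assembles both genomes of the co-culture
(2 contigs, 200 kb); every bait read maps, marking the target's contig;
step 3 recovers the ~5,000 long reads on it (half the platform-A input —
the target's share); step 5 picks the ~20,000 short reads co-assembled
with them; the re-assembly is a single 100 kb contig.  The evaluation
confirms that every picked read is target-labelled (precision 1.0), that
99.9% of pickable target reads were recovered, that the final contig
contains every target 31-mer, and that it contains no contaminant-only
k-mers.

A command-line interface wrapping these functions is installed with the
package (`exec/diffpickr`), with subcommands `simulate`, `trim`, `pick`,
`stats`, `ani`, `crispr` and `evaluate`; every stochastic subcommand
accepts `--seed`, flags override config-file keys, and JSON run reports
are written via `--report`.

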