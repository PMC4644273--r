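---
title: "Recovering a target genome from co-culture sequencing by differential read picking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recovering a target genome from co-culture sequencing by differential read picking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Some bacteria — strictly anaerobic dehalorespirers such as *Dehalococcoides*
are the canonical case — grow so poorly in pure culture that a single
cultivation yields too little DNA for direct shotgun sequencing.  Two
imperfect sources of sequence are usually available instead:

* a **whole-genome-amplification (WGA) library** from the scarce pure
  culture.  Multiple-displacement amplification produces enough DNA, but
  the reads are unsuitable for assembly on their own: a substantial
  fraction are *chimeric* (they join two non-contiguous genomic loci) and
  coverage is strongly uneven;
* **direct-shotgun (DS) libraries** from a co-culture in which the target
  grows robustly alongside a helper organism.  These reads are clean but
  mixed: roughly half derive from the wrong genome.

Differential read picking combines the two: the chimera-rich WGA reads are
used only as *bait* to label which co-culture contigs belong to the
target, and the clean DS reads carried by those contigs are recovered and
re-assembled.  Chimeras are harmless in the bait role — a read that maps
over only part of its length still votes for the right contig — which is
precisely why the method works where direct assembly of the WGA library
fails.

## The procedure

`run_pipeline()` executes six steps, mirroring the two-round structure of
the original protocol:

1. assemble the long single-end DS reads (platform A) into contigs;
2. assign the WGA bait reads to those contigs;
3. recover the platform-A reads placed on bait-supported contigs —
   these are taken to originate from the target;
4. co-assemble the recovered A reads with the quality-trimmed,
   coverage-subsampled short paired-end DS reads (platform B, plus
   QC singletons);
5. pick the platform-B reads that co-assembled with picked A reads,
   operationalised as: their placement contig carries at least one picked
   A read.  Pairs are picked or dropped atomically; a read whose mate was
   lost in QC is picked as a single;
6. re-assemble all picked reads into the final assembly.

Each step logs its read and base counts to stderr so a run can be audited
step by step.  The original protocol closed the genome by manual
curation; this package deliberately does not automate joining and instead
emits a `scaffold_report()` of candidate contig junctions ranked by
mate-pair support, leaving the decision to the analyst.

## Internal assembler and mapper

The original work used a proprietary assembler/mapper.  The package ships
its own replacements, built for read *binning* rather than assembly
polish:

* `assemble()` — a de Bruijn assembler over canonical k-mers (default
  `k = 31`) that keeps k-mers seen at least `min_kmer_count` times
  (default 2), clips tips shorter than `tip_max_len` (default `2k`), and
  emits maximal non-branching paths of length ≥ 2k.  Contig order is
  deterministic: length descending, then the lexicographically smaller of
  sequence and reverse complement.
* `assign_read()` — k-mer voting: a read is assigned to the contig/strand
  collecting the largest fraction of its k-mers, if that fraction reaches
  `min_frac`.  Ties are left unassigned, protecting picking precision.
  DS reads use `min_frac = 0.5`; bait reads use `0.3` and a shorter
  k (`k = 21`), because a chimeric bait legitimately matches over only
  part of its length.

One numerical choice deserves emphasis.  With substitution errors, the
k-mer multiplicity histogram is bimodal: an error peak at multiplicity 1–2
and a coverage peak near the sequencing depth.  At high depth the same
sequencing error recurs by coincidence in independent reads, so a fixed
multiplicity cutoff of 2 leaves thousands of short false branches in the
graph and fragments the unitigs.  When `auto_min_count = TRUE` (the
pipeline default) the cutoff is raised to the valley between the two
peaks — the classical coverage-cutoff rule used throughout the assembly
literature.  The rule only engages when a clear coverage peak (≥ 8×)
exists, so error-free or low-coverage desk-scale uses are untouched.  No
bubble popping or error correction beyond this filter is attempted: the
pipeline's purpose is binning, and its assemblies should be judged by
k-mer completeness, not contiguity.

## The synthetic co-culture generator

`simulate_coculture()` generates the full study design with truth labels:
two i.i.d. random genomes (default 100 kb each, G+C 0.47, circular), DS
libraries on both platforms, and a WGA bait library from the target.
Defaults:

| parameter | default | meaning |
|---|---|---|
| platform A read length | Normal(400, 80) bp | long single-end reads |
| platform B read length | 251 bp fixed | paired-end, insert Normal(500, 50) |
| substitution error rate | 0.005 /base | both platforms |
| qualities | Normal(37 − 0.02·pos, 2), clamped to 2–40 | Phred+33 |
| coverage A / B / WGA | 40× / 200× / 10× | totals; split by abundance |
| abundance | 0.5 / 0.5 | so each organism sees 20× (A) and 100× (B) |
| `wga_chimera_rate` | 0.1 | fraction of chimeric bait reads |
| `wga_bias_sigma` | 0.8 | lognormal σ of 5 kb window weights |

The chimera model joins two independently drawn loci (uniform junction
point along the read, either strand) — the simplest model that reproduces
the failure mode WGA inflicts on assembly.  Amplification unevenness is
modelled as a lognormal weight per 5 kb window; no attempt is made to
model MDA branch structure.  The WGA chimera rate is a free parameter (no
measured value exists for the original libraries); 10% is a realistic
order of magnitude for MDA libraries.  The error model is
substitution-only: platform-specific indel or homopolymer errors, PCR
duplicates, and more than two organisms are out of scope.  Fragments may
wrap the origin of circular genomes; a wrapping truth interval is stored
with `end > genome length` so that chimeric truth rows remain the only
rows with two intervals.

Because the genomes are i.i.d. random sequence, the two organisms share
essentially no k-mers.  Passing tests on this scenario therefore
demonstrate the machinery of the method, not its robustness to homology:
real genomes share mobile elements and conserved operons.  The
`shared_frac` knob implants an identical segment into the contaminant to
probe exactly this failure mode, and the test suite checks that precision
degrades (and never improves) as sharing rises from 0 to 10%.

## Quality trimming

`trim_read()` implements sliding-window trimming with the conventional
defaults (`q_threshold = 20`, `window_frac = 0.1`, `min_length = 20`): the
5' region before the first window whose mean quality reaches the threshold
is removed, as is everything from the start of the first subsequent window
whose mean falls below it.  Window size is `round(window_frac × length)`
with half-values rounded away from zero.  Only platform-B reads are
trimmed in the pipeline (a flag exists to override); the long platform-A
reads enter assembly untrimmed.  Trimming precedes subsampling — the
original account does not fix this order, and trimming first means the
coverage target is computed over bases that can actually contribute.

The guarantee that raising the threshold never lengthens a kept read holds
for non-increasing quality profiles (the realistic shape).  For
adversarial oscillating qualities a higher threshold can skip a noisy 5'
block entirely and legitimately keep a longer clean 3' run; the test suite
states the property over decaying profiles for this reason.

## Evaluation conventions

`evaluate_picking()` reports precision (target-labelled picked reads over
all picked; undefined when nothing is picked) and recall.  The recall
denominator is the *pickable* universe: all platform-A input reads plus
the platform-B reads that survived trimming and subsampling.  Subsampling
to 100× of a 100 kb size estimate necessarily discards about half of a
200 kb co-culture's B reads; counting those against recall would measure
the subsampler, not the picking method.  Assembly quality is measured by
exact canonical 31-mer comparison: target completeness is the fraction of
target-genome k-mers present in the final contigs, and the contaminant
fraction is the fraction of final-contig k-mers found only in the
contaminant genome.

The recovery suite runs the standard scenario at five seeds and requires
precision 1.00, recall ≥ 0.95, completeness ≥ 0.95 and contaminant
fraction ≤ 0.01.  Two 100 kb genomes keep a five-seed run within a few
minutes on one core; the method itself is scale-free in these units since
every threshold is a fraction or a per-k-mer count.

## ANIb

`anib()` fragments the query into 1020 bp windows (a trailing fragment is
kept only if ≥ 100 bp), aligns each fragment to the reference on either
strand, discards weak hits (identity < 30% or aligned query coverage
< 70%), and averages the identities of the retained fragments' best hits.
These cutoffs are the standard ANIb definitions; 95–96% on this scale
approximates the bacterial species boundary.  The alignment engine is
internal: k-mer seeding (k = 15) locates the reference window and strand,
and a local Smith–Waterman (match 2, mismatch −3, gap open 5, extend 2 —
blastn-like scoring) supplies identity (matches over alignment columns)
and coverage.  ANIb is not exactly symmetric; the package's contract,
enforced by tests, is symmetry within one percentage point on synthetic
mutated pairs, monotone decrease with substitution rate, and correct
species-threshold behaviour (3% divergence scores above 95; 15%
divergence scores below 95 or retains few fragments).

## CRISPR array detection

`find_arrays()` reports direct-repeat/spacer arrays on the forward strand
as written, with 1-based coordinates spanning first-repeat start to
last-repeat end.  Rules, all exposed as parameters: repeat length 23–55
bp, at least 3 copies, internal copies within 20% of the consensus
(terminal copies within 33%), spacer lengths 0.6–2.5× the repeat length,
and mutual spacer dissimilarity.  Detection is seeded by exact 23-mers
occurring at least three times at compliant spacing, extended to the full
repeat by column conservation (a column belongs to the repeat when at
least 90% of copies agree, rounded up so small arrays require unanimity),
then refined in three ways that matter in practice:

* *boundary polish* — seeds drawn from the subset of copies that happen to
  share a flanking base can drag a junk column into the repeat; terminal
  columns whose conservation over the full copy set falls below 0.8 are
  stripped;
* *interior repair* — a subset seed can skip an interior copy; gaps wider
  than the allowed spacer are filled with the best consensus match inside
  them, or the candidate is rejected;
* *degenerate terminal capture* — a worn first or last copy has no exact
  seed and is recovered by scanning beyond the ends at compliant spacer
  distances.

Spacer dissimilarity is deliberately a *set* property: a candidate is
rejected when more than 20% of spacer pairs reach 60% identity
(5'-aligned matches over the longer length).  Tandem-like arrays fail this
decisively, while isolated chance collisions between short random spacers
— which any strict any-pair rule trips over — are tolerated.  Hamming-type
identity is used rather than an edit-distance identity because unrelated
DNA scores ≈ 0.25 under the former and ≈ 0.5 under the latter, which
would put random spacers near the threshold.  Overlapping candidates are
resolved by more repeats, then longer span.  `consensus_repeat()` takes
the per-column majority with IUPAC codes on ties; copies of unequal
length align at their 5' ends and trailing columns require 50% occupancy.

## Genome statistics and GenBank input

`read_genbank_lite()` parses the minimal GenBank dialect needed here:
LOCUS length, ORIGIN sequence, and CDS/tRNA/rRNA/tmRNA features with
`complement(...)`/`join(...)` locations, `/pseudo` flags, and qualifiers.
Partial-location markers are treated as exact with a warning; a feature
with an unparseable location is skipped with a warning quoting it.
`genome_stats()` computes size, G+C (ambiguity codes count toward length,
never toward G+C), coding bases, and feature counts.  Coding bases are
the strand-agnostic merged union of CDS segments — the only convention
bounded by genome size, hence the only one consistent with a
"% of total ≤ 100" table; the summed alternative is available via
`coding_bp(record, union = FALSE)`.  Percentages are rounded half-up to
two decimals.  Pseudogene counting is best-effort: it reflects however
the record encodes `/pseudo`.  RNA gene counts include tmRNA when the
record annotates one, which is also the likeliest reconciliation when a
published RNA total exceeds the tRNA + rRNA sum.

## Coordinates, determinism, degenerate inputs

All interfaces use 1-based inclusive coordinates.  Every stochastic
function takes a `seed` and restores the caller's RNG state; identical
seed and configuration give byte-identical FASTQ output and identical
assemblies (contig sets are compared up to reverse complement, with a
fixed canonical ordering).  Degenerate inputs follow explicit
conventions: empty read sets assemble to an empty `Assembly`; a k above
every read length is an error; empty picks give `NA` precision and zero
recall; a genome with no CDS has zero coding bases; a sequence without
arrays returns an empty list.

## Known limitations

The assembler does not resolve repeats longer than k and performs no
scaffolding, so a single-contig reconstruction is only expected for
repeat-sparse genomes; the simulator's substitution-only error model
flatters platforms whose dominant error is indels; the CRISPR seeding
requires one exact 23-mer shared by at least three copies, so arrays
whose every copy diverges everywhere would be missed; and the picking
method inherits its one fundamental failure mode from the biology —
sequence shared between target and contaminant is picked along with the
target, which no parameter setting can fully undo.
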