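---
title: "Quantifying species composition by reference read counting"
author: "AFSeq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying species composition by reference read counting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(AFSeq)
```

## The problem

A sample of mixed biological material -- a sausage, a feed pellet, an
environmental swab -- contains genomic DNA from every species that went into
it, in rough proportion to the amount of tissue each contributed. Untargeted
deep sequencing of that total DNA therefore carries a quantitative species
signal that targeted PCR assays cannot give: every genome is sampled, not
just the loci a primer panel happens to amplify. AFSeq turns such a read set
into a species composition table by counting reads against a panel of
reference genomes, and flags unexpected species among the residual unmapped
reads by taxonomic classification of similarity-search hits.

## The quantification model

Reads are mapped against all panel genomes simultaneously and every read
falls into one of three classes per mapping round:

* **unique** -- hits exactly one genome within the round's mismatch
  allowance; counted directly for that genome;
* **multi-mapped** -- hits two or more genomes (conserved sequence);
* **unmapped** -- forwarded to the next, more permissive round, and after
  the last round to the metagenomic stage.

Two standard strategies differ only in their mismatch schedule. *AFS-quant*
maps iteratively at allowances 0, 1, 2, 3, each round re-mapping only the
reads the previous round left unmapped; it recovers the most reads and gives
the best quantification. *AFS-spec* performs a single round at 0 mismatches;
it is maximally specific (important when near-identical genomes, e.g.
congeneric species, are in the panel) at some cost in quantification
accuracy.

A multi-mapped read with candidate genome set $S$ cannot be placed with
certainty, but discarding it would bias the composition against species with
conserved genomes. It is therefore redistributed: with $U_g$ the unique-read
count of genome $g$ pooled over all rounds, the read contributes
$U_g / \sum_{h \in S} U_h$ to each $g \in S$. If no candidate has unique
support the read is split uniformly (this happens only in degenerate panels,
e.g. an exact-duplicate genome, and is logged). Redistribution conserves
reads exactly: the augmented counts sum to unique + multi.

Draft reference genomes contain runs of ambiguous bases (N). Reads
originating from the true genomic sequence underlying those runs cannot map,
deflating that species' count. The quality factor
$$f = \frac{n + c}{c},$$
with $c$ the total reference length and $n$ its number of ambiguous
positions, rescales each genome's count under the assumption that reads are
lost in proportion to the masked fraction. $f \ge 1$, with equality for a
fully resolved reference. Corrected counts are converted to percentages and
renormalized to sum to 100; the pre-renormalization total (which can exceed
100 after correction) is reported separately as `rawTotalPercent()`.

Normalization by genome *size* is available (`sizeNormalize`) but off by
default: read counts from total DNA scale with each species' DNA content per
gram of tissue, and smaller genomes correlate with smaller, more densely
packed cells, which empirically compensates much of the difference.

## The mapper

The built-in mapper is a seed-and-verify Hamming aligner with a completeness
guarantee. All N-free seeds of length $s$ (default 20) of every genome are
indexed. A read of length $L$ queried at allowance $k$ is split into $k + 1$
non-overlapping seeds: since at most $k$ positions differ in any admissible
alignment and each can spoil at most one seed, at least one seed matches
exactly (pigeonhole). Exact lookup of all $k + 1$ seeds on both strands,
followed by full Hamming verification of every candidate window, therefore
enumerates *every* alignment with at most $k$ mismatches -- the property the
unique/multi classification rests on, and the one the test suite checks
against an exhaustive brute-force scan. Preconditions: $s \ge 10$ and
$(k + 1)\,s \le L$; shorter reads are reported unmapped with a warning
rather than mapped without the guarantee. A reference N mismatches every
read base, so reads never map across masked runs; the deflation this causes
is exactly what the quality factor compensates.

A genome counts as "hit" if it has at least one admissible alignment in the
round -- not only at the best mismatch stratum. Uniqueness is a property of
the genome *set*, not of alignment scores; within-genome multiplicity is
recorded but irrelevant downstream. External mappers can substitute via
`readSam()`/`assignmentFromAlignments()`; the SAM writer/reader round-trips
read id, genome, position, strand and the `NM` mismatch count.

## The metagenomic stage

Reads left unmapped after the final round are classified from 12-column
tabular similarity-search output (the format BLAST calls `outfmt 6`/`m8`;
the search itself, typically BLASTN with word size 11 and e-value 100
against a nucleotide database, runs outside the package). Per read, the best
three hits by bitscore are kept (ties broken by smallest subject id), then:

1. reads with complexity below `minComplexity` (default 0.44) are set
   aside -- low-complexity repeats such as microsatellites occur in nearly
   every genome and attract meaningless hits;
2. hits with bitscore below `minScore` (default 75) are dropped;
3. of the survivors, only hits within `topPercent` (default 1.0) percent of
   the read's best bitscore are retained;
4. the read is assigned to the lowest common ancestor (LCA) of the
   surviving hits' taxa -- a species when the hits agree, a genus, family or
   higher group when they do not.

The complexity measure is this package's own: Shannon entropy of the
overlapping trinucleotide distribution normalized by
$\log_2(\min(64, L-2))$. The classifier whose parameter set these defaults
mirror does not document its internal measure, so ours is a stated stand-in;
under it, the 0.44 threshold cleanly separates simple repeats
(homopolymer = 0, dinucleotide repeat $\approx 0.17$) from random sequence
(mean $> 0.9$).

Taxa supported by `minSupport` (default 50) or fewer reads are folded into
their nearest supported ancestor, recursively ("more than 50" is strict);
folding conserves reads, and a `discard` mode drops them instead. Taxa whose
final count exceeds `promoteThreshold` are recommended for **promotion**:
their reference genome, if available in a panel library directory, is added
to the panel and the mapping stage re-runs. This closes the loop that turns
"unexpected species detected" into "unexpected species quantified" -- the
qualitative LCA tallies themselves are *not* quantitative, as database
representation varies wildly across taxa. `promoteThreshold` defaults to
500 reads, a deliberately conservative package choice (the procedure it
automates named no number).

## The simulator

The synthetic module generates the validation conditions end to end:

* **Genome panels.** Genomes in one group derive from a common random
  ancestor (GC fraction configurable, default 0.42), each an independently
  mutated copy at per-site divergence $d$; two copies then differ at an
  expected $2d(1-d) + 2d^2/3$ of sites. The validation panels use
  $d = 0.05$, i.e. pairwise divergence $\approx 9.7\%$ -- a stand-in for
  real food-relevant mammals, whose neutral-site divergence is at least
  about 7%. Groups model kingdoms: a "bacterial" genome is an unrelated
  random sequence. N-masking places contiguous blocks of geometric length
  (mean 1 kb, a package choice; real draft-assembly gap geometry is not
  modeled) to a requested fraction.
* **Reads.** Fixed-length reads (100 bp default, 50 bp supported) drawn
  uniformly from N-free windows on either strand, with i.i.d. substitution
  errors at rate 1% (no indels -- the error model being emulated is a flat
  substitution rate) and constant top quality in FASTQ output. Every read
  carries its origin species, source position and strand in a ground-truth
  table, so mapping accuracy is measurable exactly. Reads are drawn only
  from non-N windows: real reads contain no reference Ns, and this isolates
  the quality-factor effect in the *reference*'s masked fraction.
* **Mixtures.** Component percentages with `exactCounts = TRUE` (the
  default, used by all validation runs) allocate reads by largest-remainder
  rounding, so the declared composition is exact and observed deviations
  measure the method, not multinomial sampling noise.
* **Hit fixtures.** For the LCA stage, synthetic 12-column hit files give
  each read one hit to its true leaf taxon plus optional lower-scoring
  confounder hits, making the filter/LCA/folding chain testable without a
  sequence database.

Everything is deterministic under the supplied seeds, to the byte in the
FASTA/FASTQ outputs.

What the simulator does **not** emulate: quality-dependent and
platform-specific error profiles, indels, adapter contamination, repeat
structure and satellite DNA (the dominant source of real unmapped reads),
uneven coverage, and intraspecific polymorphism. Passing the simulated
validation therefore shows the *pipeline logic* is correct under its stated
assumptions; accuracy on real libraries additionally depends on reference
quality and tissue-dependent DNA yield, which are outside the model.

## Numerical and design choices

* Multi-read redistribution uses unique counts pooled over all rounds and
  is applied once after the final round, with weights renormalized within
  each read's candidate set. Per-round redistribution would be a defensible
  alternative; pooling is more stable at small unique counts.
* The quality factor is applied after redistribution, to the augmented
  counts.
* Proportions are renormalized to 100 after correction; the raw total is
  reported alongside rather than silently discarded.
* Relative difference against a declared target of 0 (decoy rows) is
  reported as `n.a.`; decoy genomes are panel members like any other, with
  no special casing.
* Tie-breaks are deterministic everywhere (lexicographic subject ids in hit
  truncation; candidate-set signatures in redistribution), so identical
  inputs and seeds give byte-identical reports.
* Degenerate inputs fail loudly: empty panels, all-zero counts, duplicate
  read ids and missing quality records are errors; zero-unique-support
  candidate sets and unmappable subject ids are logged fallbacks.

## Validation scale

The packaged validation (test suite and `scripts/acceptance.R`) runs the
six-genome mixture at 1 M reads on 1 Mb genomes and the four-genome
promotion scenario at 850 K reads (200 K in the test suite), with the
saturation analysis at 50 K/200 K/1 M subsamples and mapper--oracle
equivalence on 5 kb panels. One-megabase genomes keep a full run in the
minutes range while leaving per-species read counts (10 K reads for a 1%
component at 1 M reads) large enough that the sub-0.2-percentage-point
accuracy the method is expected to deliver is actually resolvable.

## Limitations

Hamming-only alignment (no gaps) is faithful to the mismatch-schedule model
but blind to indel variation; paired mates are mapped independently and
counted as two reads; the LCA stage consumes externally produced hit files
and does not run the database search; and quantification accuracy on real
samples is bounded by matrix effects (tissue-dependent DNA content) that no
read-counting method can correct without calibration tables.
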