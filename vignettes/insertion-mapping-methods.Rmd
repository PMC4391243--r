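---
title: "Methods: transposon insertion-site mapping and pool comparison"
author: "tnseqr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: transposon insertion-site mapping and pool comparison}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tnseqr)
```

## The experiment this package models

Saturated transposon mutagenesis (Tn-seq / TraDIS-style experiments)
disrupts a bacterial population with a mobile element such that, ideally,
every non-essential position in the genome is hit in some mutant. Sequencing
*junction reads* -- reads that span the transposon terminus and the flanking
genomic DNA -- localizes each insertion to a single base. Genes that tolerate
no insertions in a saturated library are candidate essential genes; genes
whose mutants disappear after a selective condition are conditionally
essential.

The pipeline has four stages, each usable on its own:

1. **Read preparation** ([prepReads()]): find the transposon terminal motif
   in raw FASTQ (both orientations; the reverse complement is derived
   automatically) and emit the genomic fragment adjacent to the junction.
2. **SAM processing** ([callInsertions()]): filter alignments of those
   fragments by MD-tag mismatch count and AS-tag score, record the
   junction-adjacent base per read, collapse target-site-duplication twins,
   and tabulate unique insertion positions with read depth.
3. **Counts** ([summarizeGenes()]): join positions to GFF annotation and
   compute per-gene statistics (NRM, NIM, centiles) and the genome-wide
   NIindex profile.
4. **Compare** ([comparePools()]): contrast an input and an output pool at
   shared positions with a standardized log-proportion-ratio Z-score.

Alignment itself is deliberately external: any aligner that writes standard
SAM with MD and AS tags can sit between stages 1 and 2. [runAligner()]
wraps `bwa mem -t 2` (default) and `bowtie2 --end-to-end --very-sensitive`;
[oracleAlign()] is an exact-match reference aligner used by the test suite.

## Read preparation

A junction read is `[vector/transposon] + motif + genomic fragment`. The
fragment immediately after a forward motif match is extracted as-is; for a
reverse-complement match the bases *before* the match are
reverse-complemented (and qualities reversed), so the emitted fragment
always reads 5'→3' away from the transposon and a single aligner convention
serves both orientations.

Deterministic tie-breaks, logged rather than configurable: the leftmost
occurrence wins within an orientation, and a forward match beats a
reverse-complement match in pathological palindromic cases. Matching is
exact -- no mismatch allowance -- because exact counts stay interpretable;
an `N` never matches. Retention bounds default to **20--50 bp**: shorter
fragments map ambiguously, and capping the length keeps the fragment from
re-entering transposon sequence on the far side of small genomic inserts.
Truncation keeps the bases *closest* to the junction, because the
junction-proximal base defines the insertion coordinate.

For paired-end input both mates observe the same junction, so when both
survive extraction only mate 1 is kept (the choice of mate is a convention;
keeping both would double-count the insertion). Gzip input is detected by
magic bytes, not file extension. Every run writes a conservation ledger:
`input = emitted + no_motif + too_short + mate_discarded`.

## SAM processing

Mismatches are counted from the **MD tag** as substituted bases only.
Letters inside a `^`-prefixed run are reference bases deleted from the
read, and insertions are invisible to MD, so neither indel type counts.
The mismatch threshold accepts a whole number of bases or a fraction in
(0,1) of the read length; the fractional form uses
`floor(frac * read_length)`, reading "10% of bases may mismatch" as an
upper bound. The **AS tag** supplies the score filter; records without AS
fail it (they cannot be vouched for). Secondary and supplementary
alignments are ignored so each read contributes at most once; this is the
conservative reading of "confidently mapped". The recommended stringent
setting for real libraries is 0 mismatches with score ≥ 50 on the bwa
scale; bowtie2 scores are negative, and score flags accept `neg10`-style
tokens because shells mangle leading minus signs.

The insertion coordinate is the base adjacent to the transposon: SAM POS on
the + strand, and POS + CIGAR reference span − 1 on the − strand (the
fragment's 5' end maps rightmost there). M/D/N/=/X consume reference;
soft clips do not.

**Collapsing.** An element that makes a target-site duplication on insertion
(exactly 8 bp for pGhost9::ISS1-type elements) yields two junction sites
exactly that distance apart. [collapseSites()] merges pairs at exactly
distance *d* into the lower coordinate with summed depth, in a single
left-to-right pass without re-chaining: the duplication produces exactly one
partner site, so longer chains are artifacts, and in `{100, 108, 116}` with
d = 8 only 108 folds into 100. Whether the twin depths should be summed or
averaged is not dictated by the chemistry; summing preserves read
conservation, so depths are summed. The pipeline collapses *before* any
coverage filtering, since the two operations do not commute.

## Counts and normalizations

A site belongs to a gene when its position lies inside the annotated span,
boundaries inclusive; a site inside overlapping genes is counted in each
(and flagged) rather than silently dropped. Gene length is the annotated
span. For GFF input, `CDS` features are preferred over `gene`, and the
identifier is the first of `ID`, `locus_tag`, `gene_id`.

Per gene:

* **NRM** (normalized reads mapped) =
  `(reads / length_kb) / (total mapped reads / 1e6)`
* **NIM** (normalized insertions mapped) =
  `(unique insertions / length_kb) / (total unique insertions / 1e6)`

Both are scale-invariant (doubling all counts and totals changes nothing),
so they compare across genes and sequencing depths. The denominators are
*genome-wide* totals of the (optionally coverage-filtered) table; genic-only
totals would make each gene's score depend on annotation completeness.
`NIM < 2` (strict) flags a candidate essential gene. Genes with zero
insertions stay in the table with NIM 0 and absent centiles -- they are the
candidates of interest. The coverage filter (`minDepth`) defaults to 1
(off) so nothing is dropped silently; 2 is the recommended setting for real
libraries, where single-read positions are enriched for noise.

**Centiles** locate an insertion within the coding sequence, 5'→3':
`100 * (offset + 1) / length`, with the offset counted from the annotated
start on + genes and the annotated end on − genes. Centiles are
strand-aware because positional bias questions ("do insertions avoid gene
starts?") are about the protein, not the chromosome.

**NIindex** is `observed − expected` per site with a single pool-wide
expectation, total mapped reads / unique positions; it sums to zero exactly
by construction, and a 201-site running mean (cosmetics only; raw data are
always emitted) highlights hot and cold regions.

## Pool comparison

At each position shared by the input and output pools, the proportion ratio
is `(input depth / input total) / (output depth / output total)`, using each
pool's total mapped reads as denominator (the plainest reading of "share of
reads mapped at a location"; the choice is recorded in the run log). Its
natural log over all shared sites is approximately normal, and

```
Zscore = (log(proportion ratio) − shared mean) / shared sd
```

with the *sample* (n−1) standard deviation -- the population sd is being
estimated, though the difference is negligible at realistic n. By
construction the Z-scores have mean 0 and sample sd 1. Flags follow fixed
two-sided normal bands: `***` at |z| ≥ 3.291 (~p = 0.001), `**` at ≥ 2.579
(~p = 0.01), `*` at ≥ 1.960 (~p = 0.05). The 2.579 edge is kept as printed
in the scheme this implements; the conventional quantile is 2.576, and the
difference is documented rather than silently corrected. No
multiple-testing correction is applied -- the flags are an approximation of
importance, not calibrated p-values; replicate-aware dispersion modelling
(edgeR-style) is a different tool's job. Sites absent from one pool go to
the input-only/output-only tables with depths and annotation but no
Z-score, which is undefined off the shared population.

## The simulator

[simulateLibrary()] generates the study conditions every guarantee is
tested under: a uniform-random genome with non-overlapping genes on
alternating strands, planted insertions, and junction reads
`motif + fragment` with constant high quality. Its defaults are the
conditions the test suite and acceptance script use: a **500 kb** genome,
**400** genes, **5,000** insertions, **8 bp** TSD, **60 bp** reads (10 bp
motif + 50 bp fragment, matching the 20--50 retention window), geometric
read depth with **mean 5** per insertion (pools of 10--20k mutants at
typical sequencing depths imply single-digit mean junction coverage),
reverse-orientation junctions at 50%, and error rate 0.

Two constructions make exact recovery provable rather than probabilistic:

* **Spacing.** Planted positions keep a minimum gap of `2·tsd + 1` bp, so
  the forward/reverse junction sites of *distinct* mutants can neither
  coincide nor sit exactly the collapse distance apart. Real libraries can
  have closer insertions; this is a stated limitation, not a claim about
  biology.
* **Motif scrubbing.** Chance occurrences of the motif in a random genome
  (~1 per 500 kb for a 10-mer) are removed by complementing the middle base
  of each hit (deterministically, preserving seed reproducibility), so the
  transposon terminus is unambiguous in every read.

The truth table records, per insertion, the planted forward junction and
the *canonical recoverable coordinate*: an insertion sequenced only from
its reverse junction is observable only at the displaced site, and the
truth table says so instead of pretending otherwise.

What the simulator does **not** emulate: Illumina error profiles (errors
are uniform substitutions, never in the motif), PCR duplicates, insertion
hot-spot sequence preference, and repetitive genomes (fragments are unique
by construction, so the exact-match oracle aligner can refuse ambiguity).
Passing the round-trip test therefore demonstrates the pipeline's
bookkeeping is exact, not that a real repetitive genome maps cleanly.

## Numerical and degenerate-input choices

* Fractional mismatch thresholds floor; collapse merges to the lower
  coordinate; d = 0 and minDepth = 1 are identities.
* A motif at the very end of a read gives a zero-length fragment,
  rejected as `too_short`.
* Empty pools are errors in partition/compare; disjoint pools skip the
  Z-score stage with a warning; shared sd = 0 sets all Z-scores to 0 with
  a warning rather than dividing by zero.
* An empty FASTQ yields empty QC tables and a warning, not an error.
* All coordinates are 1-based inclusive, matching SAM and GFF.

## Problem sizes

The test suite runs the full round trip at 5,000 insertions on 500 kb
(about 25,000 reads) and the null calibration at 2,000 shared sites, sizes
at which every guarantee is exercised meaningfully while a complete run of
suite plus acceptance script stays around a minute on one core. The same
code paths scale linearly in reads and positions for real libraries.
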