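---
title: "Gene-structure statistics over a relational annotation model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene-structure statistics over a relational annotation model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genestats)
```

## The model and its assumptions

`genestats` treats genome annotation as a small relational database
rather than a feature stream. Three tables carry the primary data: a
*genes* table (identity, type, RefSeq curation status, annotated span), a
*transcripts* table (accession, parent gene, transcript-level status —
which may legitimately differ from the gene's), and a *rows* table with
one record per exon of each transcript, carrying the coding part of that
exon and the downstream intron when one follows. Everything else —
mature mRNA, CDS and UTR lengths, gene spans, non-redundant sets, splice
censuses, filtered summaries — is derived from these rows.

Assumptions worth stating explicitly:

- Coordinates are 1-based and inclusive (the GFF3 convention); a length
  is always `end − start + 1`. No 0-based translation layer exists
  anywhere in the package.
- Exon ordinals follow transcription order, so on the minus strand
  exon 1 has the largest genomic coordinates. "First", "internal" and
  "last" exon classes, and the 5′/3′ UTR directions, are biological, not
  genomic.
- Each transcript owns its exon chain. Introns are therefore
  isoform-specific: two isoforms of one gene can imply different introns
  over the same locus, and UTR lengths must be computed per isoform
  across that isoform's own intron structure.
- The CDS includes the stop codon; CDS segments are taken exactly as
  annotated.
- A gene may have no transcripts at all if it has an annotated span
  (tRNA-style records). Its transcript-level features are *missing*,
  never zero, and its length falls back to the span.

## Derived features and their conventions

The 5′ UTR of a coding transcript is the count of exonic bases strictly
upstream, in transcription direction, of the first coding base; the
3′ UTR mirrors it downstream of the last. Internally the per-exon coding
parts are mapped into transcript coordinates and the UTRs read off the
first and last coding positions, which makes
`mature = utr5 + cds + utr3` an identity for coding transcripts with a
contiguous CDS. The test suite checks this arithmetic against a
brute-force labeler that enumerates every exonic base and labels it
UTR5/CDS/UTR3 individually, over a thousand random transcripts on both
strands (1–30 exons), plus fixed worked examples on each strand.

For transcripts whose CDS is *not* contiguous in transcript space (some
dialects encode programmed frameshifts this way), exonic bases between
CDS segments are counted in neither UTR nor the CDS length; such
transcripts are flagged (`cds_noncontiguous`) rather than rejected. A
disconnected coding region *within a single exon* cannot be represented
as a row's single coding part and is a hard error.

A gene's length is the envelope of the union of its transcripts' exons
(`max end − min start + 1`). Annotation rarely defines "gene length"
crisply; the envelope reproduces gene-span semantics, is computable in
both input dialects, and degrades gracefully to the annotated span for
transcript-less genes. The "isoform with the most exons" reported per
gene breaks ties by lexicographically smallest accession, for
determinism.

Abutting exons (zero intron gap) raise an error instead of being merged
silently: they are annotation defects, and merging would corrupt intron
statistics downstream.

## Non-redundant sets

Exons, coding exons and introns shared by isoforms collapse on exact
`(chrom, strand, start, end)` identity. Two choices were genuinely open:

- *Coding exons dedup on the coding subinterval*, not the whole exon.
  Two isoforms sharing an exon but differing in CDS start must
  contribute two coding-exon members; a full-exon key could not produce
  distinct non-redundant exon and coding-exon counts.
- *Collapsing is genome-wide*, not per-gene: identical intervals claimed
  by two genes collapse once, with both in the provenance list. The
  counts are set cardinalities over coordinates; cross-gene coordinate
  identity is rare in practice and visible in provenance when it
  happens.

Only exact identity collapses — partial overlap clustering ("meta-exons")
is out of scope.

## Dynamic statistics

Every summary is `summary_stats()` over a value vector with parallel
record identifiers: n, median, mean, sample SD, total, and min/max each
paired with *all* ids attaining them (a summary that cannot say *which*
gene is shortest is of limited use). Conventions: median of an even
count is the midpoint of the two central order statistics; SD uses the
n−1 denominator and is missing for n = 1; an empty subset yields missing
values, not zeros. Percentages are kept at full precision internally and
display-rounded half-up to 2 decimals.

Filters are conjunctions of typed clauses (equality, set membership,
inclusive numeric range, prefix/suffix/substring, and a cross-table
"gene has a transcript with status in S" clause). The engine guarantees
the dynamic-recompute contract: for any filter, the summary of the
filtered subset equals the plain summary of the brute-force-filtered
value list; the tests assert this with randomized filter specifications.

The curated-subset rule bundles the standard quality selection: gene
status REVIEWED or VALIDATED, in the current annotation release, at
least one REVIEWED/VALIDATED transcript, and — at transcript level —
only NM_/NR_ accessions, excluding pipeline-model XM_/XR_ records.

## Sequences and the splice census

Sequence extraction always returns transcription orientation
(minus-strand intervals are reverse-complemented) and is checked against
chromosome bounds before any mutation of the annotation set. FASTA is
uppercased on load; soft-masking is discarded since the statistics are
mask-agnostic. Chromosome names tolerate a leading `chr` mismatch
between annotation and FASTA, the single most common interoperability
failure (exact matching can be forced).

The splice census classifies the first and last two bases of each intron
of length ≥ 4 into six categories — GT–AG, GC–AG, AT–AC, GT–other,
other–AG, other–other — which partition all donor/acceptor pairs.
`N` bases (assembly gaps) fall into the "other" classes rather than
erroring. Shorter introns are counted as excluded, never classified.

## Quality-control flags

`qc_flags()` flags but never drops: introns under 30 bp (no validated
intron of any species is shorter; sub-30 bp records are artefacts),
exons under 2 bp, coding transcripts with a 0 bp UTR at either end
(often only the CDS was registered), CDS lengths not divisible by 3
(annotated CDSs may be incomplete — this is deliberately a flag, not an
invariant), and non-contiguous CDSs. Whether flagged records are
excluded from a given statistic is the caller's filter choice, because
the underlying curation is manual, not algorithmic.

## The synthetic generator and what passing tests mean

`make_fixture()` builds a deterministic genome + annotation pair with a
truth manifest. Transcripts are designed in transcript space first —
mature length, UTR/CDS split (CDS forced to a multiple of 3, UTRs drawn
from 10–150 bp), exon/intron lengths (40–400 bp and 50–1500 bp), isoform
structure (alternative isoforms keep each template exon with
probability 0.75 and sometimes shift their start boundary) — and then
mapped onto chromosomes, so every expected feature value is known by
construction, not by running the pipeline. Splice categories are
apportioned to unique introns by largest remainder (so planted class
counts are exact when isoforms do not share boundaries) and the
dinucleotides are written into the genome; the manifest census is then
re-read from the final sequence with generator-local code, which keeps
it authoritative even where isoform boundary overlap lets one write
clobber another. Default scale is 200 genes on 3 chromosomes (~500–600
transcripts, a genome of a few hundred kb); the acceptance tests run
five seeds at this scale, which keeps the full suite around a minute
while still exercising thousands of rows per replicate.

The generator emulates the *relational* structure of a curated gene set:
multi-isoform genes with shared exons, strand mixtures, status mixtures
with model records, transcript-less genes, planted splice classes,
planted intron-suffix motifs, and optional planted QC anomalies. It does
not emulate realistic human length distributions (human intron lengths
are heavy-tailed over four orders of magnitude), GC/repeat content,
overlapping genes, or fuzzy coordinates. Passing the manifest-recovery
tests therefore demonstrates that the pipeline's arithmetic, collapsing
and classification are exact on data whose truth is known — not that
any biological distribution is reproduced.

## Published reference totals

`human_gene_totals()` carries the printed aggregate totals of a
January-2016 survey of the curated human nuclear gene set (total
chromosome length 3088.27 Mb; protein-coding and non-coding gene-length
totals; non-redundant exon and coding-exon totals; the splice census of
414,385 intron sequences; curated gene and transcript counts).
`check_human_fractions()` re-derives the survey's twelve headline
percentages from those totals with the package's fraction arithmetic and
half-up rounding at the printed precision, and `scripts/acceptance.R`
writes them as JSON. These are arithmetic reproductions from printed
inputs; recomputing the totals themselves requires the corresponding
annotation snapshot and chromosome sequences, which are external runs
(`read_gff3` + `genome_fraction_report`) rather than part of the test
suite.

## Known limitations

- GTF is not parsed; GFF3 and the native dialect are the interchange
  formats.
- Inputs are loaded in memory; there is no streaming or indexing.
- Alternative haplotype placements, fuzzy coordinates and trans-splicing
  are out of scope.
- Splice-strength scoring and branch-point detection are out of scope;
  the census is purely dinucleotide-based.
- Unknown-strand (`.`) transcripts are loaded with exons in ascending
  order under a warning; their transcription-order semantics are
  undefined.
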