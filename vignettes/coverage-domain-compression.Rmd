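---
title: "Coverage-domain lossy compression of spliced RNA-seq alignments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coverage-domain lossy compression of spliced RNA-seq alignments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coverpress)
```

## The model

Isoform assemblers and quantifiers consume a small slice of what a SAM/BAM
file stores: per-base coverage, splice junction placement, multi-mapping
counts (NH:i), transcriptional strand of spliced alignments (XS:A), and the
distribution of paired-end fragment spans (TLEN, measured on the genome with
introns included — we call it the *genomic outer distance*). Read names,
nucleotide sequences, base qualities, mapping qualities and most FLAG bits
have essentially no bearing on those analyses. `coverpress` therefore
discards them and keeps only a coverage-domain summary:

1. **Bundles.** Sorted alignments are grouped as a gene finder would: an
   alignment starting within 50 bases of the running end of the current
   bundle joins it, otherwise a new bundle opens. Spliced alignments extend
   the running end across their introns, so one multi-exon gene stays one
   bundle. Bundle spans approximate expressed gene loci.
2. **Partitions.** Each bundle's span is cut at every splice-site position
   observed in its alignments (junction donors and acceptors), producing
   partitions that tile the span.
3. **Buckets.** Each alignment maps to a bucket keyed by (a) the subset of
   partitions its aligned blocks touch, (b) its NH:i value and (c) its XS:A
   strand, with a dummy value for the common case of an unspliced alignment
   that carries no XS:A. A bucket stores one coverage vector over the
   *concatenation* of its spanned partitions (introns between them are
   implicit and cost nothing), a tally of read lengths, a count of
   paired ends, and a tally of |TLEN| values (one entry per pair, attached
   to the leftmost end's bucket).
4. **Serialization.** Coverage vectors are run-length encoded — extremely
   effective at low coverage — and every bundle's bucket set is compressed
   into an independent zlib-wrapped DEFLATE block. A small uncompressed
   index of bundle spans and block offsets heads the file, so targeted
   queries touch only the blocks they need.

Pairs that do not fit bundling ("unbundled" alignments) fall into four
categories: one end inside an intron of the other (biologically
implausible; split into two unpaired reads by default, preserved with
`preserve_nested`), ends on different chromosomes, ends in different
bundles of one chromosome (both preserved in *bundle-spanning buckets* in a
chunked, separately indexed archive section), and ends with contradictory
XS:A strands (by default one end, chosen by the seeded RNG, is harmonized
to the other's strand; `split_discordant` splits them instead). Orphans —
ends whose mate failed to align — become unpaired reads; their pairing is
lost by design.

## Decompression: read recovery and pairing

Decompression must invert a many-to-one summary. Per bucket we seek
intervals whose lengths come from the stored tally, whose stacked coverage
never exceeds the stored vector at any base, and whose total length is
maximal. The problem is NP-hard in general (it embeds multiple subset sum)
and can be ambiguous even when solvable — a flat stretch of coverage 1 of
width $l_1+l_2$ admits two decompositions into reads of lengths
$l_1 \ne l_2$ — so exact inversion is not promised. Two facts make a greedy
scan effective in practice: second-generation sequencing yields uniform or
near-uniform read lengths, and with a single read length the solution is
unique. The uniform case is solved in closed form here: with $d_i$ the
coverage increment at base $i$, start counts obey
$s_i = d_i + s_{i-L}$, i.e. cumulative sums of increments within residue
classes modulo the read length $L$; when the resulting $s$ is non-negative
and no read overruns the vector this is exactly the unique solution, and
the code falls back to the general scan otherwise.

The general scan works left to right. Any read covering the leftmost
uncovered base must start there, so the scan repeatedly chooses a tallied
length consistent with coverage at that point (consistent = subtracting the
read leaves no negative base). Among consistent lengths the default
tie-break prefers the longest whose removal strands no coverage fragment
shorter than the smallest remaining tallied length; because the published
description leaves the mixed-length heuristics open, the scan is also run
under three other deterministic tie-break orders plus a one-step rollout
(score each candidate by completing the scan greedily), and the solution
placing the most total length wins. Coverage fidelity is favored over
length fidelity: when no tallied length fits a residual run, a read is
artificially lengthened or shortened by up to `k_repair = 5` bases to
consume it; larger discrepancies leave coverage unconsumed rather than
fabricating wildly wrong reads. On randomized mixed-length buckets with at
most 12 reads and 3 distinct lengths the scan recovers about 97% of the
total length an exhaustive branch-and-bound solver certifies as optimal
(the acceptance suite requires at least 95%); with uniform lengths it is
exact, which the test suite asserts as precision = recall = 1 on full
round trips.

Recovered intervals in concatenated-partition space are mapped back through
the bucket's spanned partitions; wherever two consecutive spanned
partitions are genomically discontiguous the read is split and an N CIGAR
junction re-emitted, so junction placement survives compression exactly.

**Pairing.** The two ends of a fragment almost never share a bucket (their
spanned-partition subsets differ), so ends are pooled per bundle and paired
against the summed outer-distance tally. (The module contract sketches
pairing per bucket; that cannot reunite real pairs, and the bundle-level
pass matches the stored tallies it consumes — the per-bucket `paired_count`
says how many of each bucket's recovered reads enter the pool.) The greedy
pass examines unpaired reads working inward from the extremes, alternating
left and right; each read takes the most distant partner whose outer
distance still has count in the tally, both leave the pool, and the count
decrements. Leftovers are matched randomly in a second, seeded pass, up to
the recorded number of paired ends. Aggregate distance distributions are
preserved well — exactly so on feasible instances with distinct distances —
but the *identity* of pairings shuffles; pair-level precision/recall of a
round trip is accordingly much lower than end-level precision/recall, which
is the documented, intended behavior of the format, not a defect.

## Queries

Three query types run against the index without full decompression:
`query_bundles` (index only — no block inflation), `query_coverage`
(inflates only overlapping blocks, sums the relevant coverage-vector
portions mapped to genomic coordinates, never runs read recovery), and
`query_alignments` (runs recovery and pairing on overlapping bundles, then
filters by overlap). Each bundle derives its own RNG stream from the
archive-level seed, so query results are independent of what was queried
before. Coverage is the lossless core of the format: a full-genome coverage
query reproduces the source pileup base-for-base, and the acceptance suite
checks this on every synthetic dataset including paired, mixed-length,
multi-mapper, distant-pair and cross-chromosome configurations.

## Fidelity metrics

End-level precision/recall matches alignments between two SAM files on
(chromosome, start, exact junction list), each alignment usable at most
once (multiset intersection); pair-level requires both ends of a pair to
match their counterparts. Transcript-level fidelity uses an exon score
$s(e_1,e_2) = 1 - \frac{\min(|x_2-x_1|,k)}{2k} - \frac{\min(|y_2-y_1|,k)}{2k}$
with $k = 10$ by default: each boundary offset costs up to one half,
saturating at $k$ bases. Two transcripts are scored by a monotone
one-to-one exon assignment maximizing the summed exon score (a weighted
longest-common-subsequence dynamic program, validated in the tests against
brute-force enumeration of all monotone matchings), normalized by the
larger exon count so only identical exon chains score 1. Weighted
transcriptome precision sums each assembled transcript's best score against
the reference, weighted by its coverage; recall mirrors it from the
reference side. As printed, the sums are unnormalized; we divide by total
weight so a transcriptome scored against itself gives exactly 1, making
values comparable across datasets. Strand handling (opposite known strands
score 0, unknown matches either) and the exact aggregation are our
reconstruction of a procedure the source text only sketches.

## The synthetic-data generator

`gen_transcriptome` lays out non-overlapping single-transcript genes with
inter-gene gaps above the 50-base bundling threshold (so bundle boundaries
are predictable: one gene, one bundle), exon lengths 150–400, intron
lengths 60–300, one to four exons — small but structurally representative
gene models. `gen_reads` samples reads from transcript coordinates with
log-normal expression weights, projects them to genomic blocks (N CIGARs
across introns, XS:A from the gene strand on spliced reads only, matching
aligner convention), and can inject multi-mappers (NH:i:2 duplicate
placements), orphans, discordant-strand pairs and distant /
cross-chromosome pairs at controlled rates. Paired fragments draw
transcript-space lengths from a truncated normal (mean 250, sd 30 —
ordinary Illumina library geometry for 100-base reads) and record TLEN as
the genomic outer distance after projection. The generator returns exact
truth tables alongside the SAM it writes, which turns lossy-compression
testing into exact bookkeeping.

What a green test does *not* establish: the generator has no sequencing
errors, no quality strings, no soft clips or indels, no overlapping gene
models, no real expression structure, and gene-scale geometry far smaller
than a mammalian annotation. Results here certify the algorithms'
contracts, not full-scale compression ratios on real data, which depend on
aligner behavior and library size.

## Numerical and design choices

* Coordinates are 0-based half-open internally; conversion to 1-based SAM
  happens only at the I/O boundary.
* Indels are flattened: D merges into its block, I disappears, so a
  decompressed CIGAR contains only M and N, and an alignment's stored
  length is its genomic footprint. This keeps the per-bucket invariant
  (coverage mass = sum of length × count over the tally) exact, which the
  suite asserts for every bucket of every compressed dataset.
* "Very far apart" for unbundled category (iii) is operationalized as "the
  two ends resolve to different bundles" — no extra distance parameter.
* Bundle-spanning buckets store, per side, the genomic partition intervals
  their ends span (the side's own span cut at its own junctions, intron
  gaps dropped), making unbundled chunks self-contained: expanding them
  never touches bundle blocks.
* Bucket order inside a bundle is lexicographic by (spanned subset, strand,
  NH); chunk size for the unbundled section is 64 buckets; varint framing
  throughout. Same input + same seed ⇒ byte-identical archives, which the
  acceptance suite asserts.
* One archive-level seed drives every stochastic step (discordant-strand
  harmonization at compression; the random pairing pass at expansion, via
  per-bundle derived streams). Different seeds may change strand
  harmonization and pairing identities, never coverage or tallies.

## Known limitations

Recovery of mixed-length buckets is heuristic, and pairings are
reconstructed distributionally, so read identities and pair links do not
survive compression — by design. Multi-mapper locations are preserved with
their NH values, but without names the many-to-one read/alignment relation
is gone, which is known to matter for annotation-based quantification in
some downstream tools. Quality-dependent analyses (variant calling, error
modeling) are out of scope entirely.
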