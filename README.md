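# coverpress

Lossy, coverage-domain compression of spliced RNA-seq alignments, for
people who run isoform assembly and quantification at scale. Downstream
tools in that space consume per-base coverage, splice junctions,
multi-mapping counts and fragment-length statistics — not read names,
sequences or qualities — so a sorted SAM/BAM file can be reduced to a
fraction of its size if you are willing to give those up. `coverpress`
does exactly that, and quantifies what the loss costs.

## What it stores

Sorted alignments are grouped into gene-scale **bundles** (an alignment
starting within 50 bases of the running bundle end joins it). Each
bundle's span is cut at every observed splice site into **partitions**;
each alignment falls into a **bucket** keyed by (spanned partition subset,
NH:i value, XS:A strand). A bucket keeps one run-length-encoded coverage
vector over its concatenated spanned partitions, a read-length tally, and
a tally of genomic outer distances (SAM TLEN, introns included) for its
pairs. Every bundle becomes an independent zlib DEFLATE block behind an
uncompressed index, so bundle lists, regional coverage and regional
alignments can be queried without touching the rest of the file. Pairs
that span bundles or chromosomes are preserved in a separately chunked
"unbundled" section; intron-nested and strand-discordant pairs are
handled by policy flags (`preserve_nested`, `split_discordant`).

Decompression reverses the summary per bucket: **read recovery** extracts
intervals consistent with the coverage vector and length tally (exact and
unique for uniform-length data — solved in closed form; a deterministic
multi-strategy greedy scan otherwise), then **pairing** greedily rebuilds
pairs against the stored outer-distance tally, most distant first,
alternating from both extremes, with a seeded random second pass. Coverage
is lossless; read positions are near-lossless; *pair identities* shuffle
while the aggregate distance distribution is preserved — that is the
designed trade-off.

## Worked example

```r
library(coverpress)

# a 5-gene synthetic transcriptome and 1000 paired-end fragments
txome <- gen_transcriptome(n_genes = 5, seed = 42)
gen_reads(txome, n_reads = 2000, read_length = 100L, paired = TRUE,
          sam_out = "demo.sam", seed = 42)

s <- compress_sam("demo.sam", "demo.cvp", seed = 1)
#> bundles: 5  buckets: 17  bytes: 103325 -> 4747  (ratio 21.8)

arc <- open_archive("demo.cvp")
query_bundles(arc)            # gene-scale spans, straight from the index
#>   chrom start  end
#> 1  chr1  1000 1378
#> 2  chr1  1633 2644
#> 3  chr1  3275 4569
#> 4  chr2  1005 1850
#> 5  chr2  2081 2792

query_coverage(arc, "chr1", 1000, 1010)   # per-base depths, lossless
#>  [1]  1  4 10 13 13 14 18 22 23 27

decompress_archive("demo.cvp", "demo_out.sam", seed = 1)
orig <- read_sam("demo.sam")$alignments
back <- read_sam("demo_out.sam")$alignments
round(alignment_pr(orig, back, mode = "ends"), 3)
#> precision    recall
#>         1         1
round(alignment_pr(orig, back, mode = "pairs"), 3)
#> precision    recall
#>     0.028     0.028
```

The numbers tell the whole story: a 21.8× size reduction; every read end
recovered at its exact position with its exact junctions (uniform 100-base
reads make recovery exact, hence end-level precision = recall = 1); and
pair identities almost completely shuffled (pair-level 0.028) even though
each bundle's outer-distance tally is consumed faithfully — deep stacks of
overlapping fragments admit many pairings with identical distance
multisets.

## Command line

```sh
coverpress synth      --out-prefix toy --n-genes 20 --n-reads 5000 --seed 1
coverpress compress   toy.sam toy.cvp --seed 1 [--preserve-nested] [--split-discordant]
coverpress decompress toy.cvp toy_out.sam --seed 1
coverpress query      --mode bundles    toy.cvp              # BED to stdout
coverpress query      --mode coverage   --chrom chr1 --start 1000 --end 2000 toy.cvp  # bedGraph
coverpress query      --mode alignments --chrom chr1 --start 1000 --end 2000 toy.cvp  # SAM
coverpress fidelity   --mode ends toy.sam toy_out.sam        # TSV metrics
```

The script lives in `inst/exec/`; after installation call it via
`Rscript -e 'coverpress::cvp_main()' -- ...` or put the installed
`exec/coverpress` on your PATH. One `--seed` governs every stochastic step
(discordant-strand harmonization, random pairing), and identical seeds
produce byte-identical archives.

## Scope

Quality strings, nucleotide sequences, mapping quality and read names are
discarded by design and not recoverable. See
`vignettes/coverage-domain-compression.Rmd` for the model, the recovery
and pairing algorithms, tie-breaks, parameter defaults, and what the
synthetic-data tests do and do not establish.
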