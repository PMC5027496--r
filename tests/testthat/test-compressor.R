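test_that("rle round-trips exactly and is canonical", {
  cv <- rle_encode(c(0, 0, 3, 3, 3, 1))
  expect_equal(cv$values, c(0L, 3L, 1L))
  expect_equal(cv$lengths, c(2L, 3L, 1L))
  expect_equal(rle_decode(cv), c(0L, 0L, 3L, 3L, 3L, 1L))
  expect_equal(rle_decode(rle_encode(integer(0))), integer(0))
  expect_error(rle_encode(c(1, -1)), "non-negative")
  set.seed(5)
  for (rep in 1:50) {
    x <- sample(0:4, sample(1:200, 1L), replace = TRUE)
    enc <- rle_encode(x)
    expect_identical(rle_decode(enc), as.integer(x))
    # canonical: no two adjacent runs share a depth
    if (length(enc$values) > 1L) {
      expect_true(all(diff(enc$values) != 0L))
    }
  }
})

test_that("partition_bundle cuts at every distinct splice site", {
  # one junction (100, 200) in a [0, 300) span
  p <- partition_bundle(list(blk(0, 100, 200, 300)), 0L, 300L)
  expect_equal(p$start, c(0L, 100L, 200L))
  expect_equal(p$end, c(100L, 200L, 300L))
  # no junctions: a single partition
  p2 <- partition_bundle(list(blk(0, 100), blk(50, 150)), 0L, 150L)
  expect_equal(nrow(p2), 1L)
  # two junctions sharing a donor: shared cut deduplicated -> 4 partitions
  p3 <- partition_bundle(
    list(blk(0, 100, 200, 300), blk(0, 100, 250, 300)), 0L, 300L
  )
  expect_equal(nrow(p3), 4L)
  expect_equal(p3$start, c(0L, 100L, 200L, 250L))
})

test_that("assign_bucket keys on spanned partitions, NH and strand", {
  p <- data.frame(start = c(0L, 100L, 200L), end = c(100L, 200L, 300L))
  k1 <- assign_bucket(blk(120, 180), p, nh = 1L, strand = "*")
  expect_equal(k1$spanned, 2L)
  expect_equal(k1$strand, "*")
  k2 <- assign_bucket(blk(50, 100, 200, 250), p, nh = 3L, strand = "+")
  expect_equal(k2$spanned, c(1L, 3L))
  expect_error(assign_bucket(blk(250, 350), p), "outside all partitions")
})

test_that("build_buckets separates keys and aggregates coverage/tallies", {
  p <- data.frame(start = c(0L, 100L, 200L), end = c(100L, 200L, 300L))
  # identical unpaired reads collapse into one bucket
  a <- make_aln("chr1", list(blk(0, 100), blk(0, 100)))
  b <- build_buckets(a, p)
  expect_equal(length(b), 1L)
  expect_equal(b[[1L]]$coverage$values, 2L)
  expect_equal(b[[1L]]$coverage$lengths, 100L)
  expect_equal(b[[1L]]$length_tally, data.frame(value = 100L, count = 2L))

  # nh and strand separate buckets
  a2 <- make_aln("chr1", list(blk(0, 100), blk(0, 100), blk(0, 100)),
                 nh = c(1L, 2L, 1L), strand = c("*", "*", "+"))
  expect_equal(length(build_buckets(a2, p)), 3L)

  # spliced bucket: coverage over concatenated spanned partitions only
  a3 <- make_aln("chr1", list(blk(50, 100, 200, 250)))
  b3 <- build_buckets(a3, p)
  expect_equal(b3[[1L]]$spanned, c(1L, 3L))
  expect_equal(rle_decode(b3[[1L]]$coverage),
               c(rep(0L, 50), rep(1L, 50), rep(1L, 50), rep(0L, 50)))

  # one pair: outer distance tallied once, on the leftmost end's bucket
  a4 <- make_aln("chr1", list(blk(0, 100), blk(200, 300)),
                 paired = c(TRUE, TRUE), pair_id = c(1L, 1L),
                 tlen = c(300L, -300L), mate_start = c(200L, 0L))
  b4 <- build_buckets(a4, data.frame(start = 0L, end = 300L))
  expect_equal(length(b4), 1L)
  expect_equal(b4[[1L]]$tlen_tally, data.frame(value = 300L, count = 1L))
  expect_equal(b4[[1L]]$paired_count, 2L)
})

test_that("per-bucket conservation holds on random synthetic datasets", {
  for (seed in 1:3) {
    txome <- gen_transcriptome(n_genes = 8L, seed = seed)
    res <- gen_reads(txome, n_reads = 600L,
                     read_length = c(75L, 100L, 120L),
                     paired = seed == 2L, seed = seed + 10L)
    build <- compress_alignments(res$alignments, res$chroms, seed = 1L)
    for (p in build$payloads) {
      for (b in p$buckets) {
        expect_equal(
          sum(b$coverage$values * b$coverage$lengths),
          sum(b$length_tally$value * b$length_tally$count)
        )
      }
    }
  }
})

test_that("archives round-trip structurally and the index is sane", {
  txome <- gen_transcriptome(n_genes = 6L, seed = 2L)
  res <- gen_reads(txome, n_reads = 500L, paired = TRUE,
                   distant_rate = 0.05, cross_rate = 0.05,
                   seed = 3L)
  build <- compress_alignments(res$alignments, res$chroms, seed = 1L)
  tf <- withr::local_tempfile(fileext = ".cvp")
  coverpress:::serialize_archive(build, tf)
  arc <- open_archive(tf)
  expect_equal(arc$chroms, build$chroms)
  expect_equal(arc$bundles$start, build$bundles$start)
  expect_equal(arc$bundles$end, build$bundles$end)
  expect_true(all(diff(arc$bundles$offset) > 0))
  # every block inflates back to the bucket set that produced it
  for (i in seq_len(nrow(arc$bundles))) {
    blk_ <- read_bundle_block(arc, i)
    expect_equal(blk_$cuts, build$payloads[[i]]$cuts)
    expect_equal(length(blk_$buckets), length(build$payloads[[i]]$buckets))
    for (k in seq_along(blk_$buckets)) {
      got <- blk_$buckets[[k]]
      want <- build$payloads[[i]]$buckets[[k]]
      expect_equal(got$spanned, want$spanned)
      expect_equal(got$nh, want$nh)
      expect_equal(got$strand, want$strand)
      expect_equal(got$coverage$values, as.integer(want$coverage$values))
      expect_equal(got$coverage$lengths, as.integer(want$coverage$lengths))
      expect_equal(got$length_tally, want$length_tally)
      expect_equal(got$paired_count, want$paired_count)
      expect_equal(got$tlen_tally, want$tlen_tally)
    }
  }
  # unbundled section round-trips too
  n_unb <- sum(vapply(seq_len(nrow(arc$chunks)), function(ci) {
    length(read_unbundled_chunk(arc, ci))
  }, integer(1)))
  expect_equal(n_unb, length(build$unbundled))
})

test_that("empty input yields a valid archive with zero bundles", {
  build <- compress_alignments(
    coverpress:::empty_alignment_table(),
    data.frame(name = "chr1", length = 1000L), seed = 1L
  )
  tf <- withr::local_tempfile(fileext = ".cvp")
  coverpress:::serialize_archive(build, tf)
  arc <- open_archive(tf)
  expect_equal(nrow(arc$bundles), 0L)
  expect_equal(nrow(query_bundles(arc)), 0L)
})

test_that("format errors identify the broken section", {
  tf <- withr::local_tempfile(fileext = ".cvp")
  writeBin(charToRaw("NOPE!junk"), tf)
  expect_error(open_archive(tf), "bad magic")
  # truncate a valid archive inside the data section
  txome <- gen_transcriptome(n_genes = 3L, seed = 2L)
  res <- gen_reads(txome, n_reads = 200L, seed = 3L)
  build <- compress_alignments(res$alignments, res$chroms, seed = 1L)
  coverpress:::serialize_archive(build, tf)
  full <- readBin(tf, "raw", file.size(tf))
  writeBin(full[seq_len(length(full) - 10L)], tf)
  expect_error(open_archive(tf), "truncated")
})

test_that("DEFLATE blocks are standard zlib streams", {
  txome <- gen_transcriptome(n_genes = 3L, seed = 2L)
  res <- gen_reads(txome, n_reads = 200L, seed = 3L)
  build <- compress_alignments(res$alignments, res$chroms, seed = 1L)
  tf <- withr::local_tempfile(fileext = ".cvp")
  coverpress:::serialize_archive(build, tf)
  arc <- open_archive(tf)
  first <- arc$data[(arc$bundles$offset[1L] + 1L):arc$bundles$block_len[1L]]
  # zlib header: 0x78, deflate with 32K window
  expect_equal(as.integer(first[1L]), 0x78L)
})
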