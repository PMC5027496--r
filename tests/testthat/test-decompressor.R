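test_that("uniform-length buckets recover exactly", {
  # two stacked reads
  r <- recover_reads(rle_encode(rep(2L, 100)), tally_new(c(100L, 100L)))
  expect_equal(r, data.frame(start = c(0L, 0L), end = c(100L, 100L)))
  # staggered overlap: unique solution
  r2 <- recover_reads(rle_encode(c(rep(1L, 50), rep(2L, 50), rep(1L, 50))),
                      tally_new(c(100L, 100L)))
  expect_equal(r2, data.frame(start = c(0L, 50L), end = c(100L, 150L)))
})

test_that("the two-read ambiguity instance returns one of both solutions", {
  set.seed(31)
  for (rep in 1:20) {
    l1 <- sample(30:120, 1L)
    l2 <- sample(setdiff(30:120, l1), 1L)
    cov <- rle_encode(rep(1L, l1 + l2))
    r <- recover_reads(cov, tally_new(c(l1, l2)))
    expect_equal(nrow(r), 2L)
    expect_equal(sum(r$end - r$start), l1 + l2)
    lens <- sort(r$end - r$start)
    expect_equal(lens, sort(c(l1, l2)))
    expect_equal(r$start[order(r$start)][1L], 0L)
  }
})

test_that("recovered coverage never exceeds stored coverage (safety)", {
  set.seed(77)
  for (rep in 1:300) {
    rb <- random_bucket(sample(2:10, 1L), sample(c(30L, 50L, 80L, 100L), 2L))
    r <- recover_reads(rb$coverage, rb$tally)
    got <- induced_coverage(r, length(rb$cov))
    expect_true(all(got <= rb$cov))
  }
})

test_that("incompatible tally/coverage inputs degrade gracefully", {
  # tally demands more length than the coverage holds
  r <- recover_reads(rle_encode(rep(1L, 60)), tally_new(c(50L, 50L)))
  expect_true(all(r$end - r$start <= 60L))
  got <- induced_coverage(r, 60L)
  expect_true(all(got <= 1L))
  # coverage with no tally entries at all places nothing
  r2 <- recover_reads(rle_encode(rep(1L, 60)), tally_new())
  expect_equal(nrow(r2), 0L)
})

test_that("greedy recovery reaches >= 95% of the exhaustive optimum", {
  set.seed(13)
  tot_greedy <- 0
  tot_opt <- 0
  for (rep in 1:60) {
    rb <- random_bucket(sample(3:8, 1L),
                        sample(c(25L, 40L, 60L), sample(2:3, 1L)),
                        span = 200L)
    r <- recover_reads(rb$coverage, rb$tally)
    got <- sum(r$end - r$start)
    opt <- oracle_recover_total(rb$cov, rb$tally, incumbent = got)
    tot_greedy <- tot_greedy + got
    tot_opt <- tot_opt + opt
    expect_lte(got, opt)
  }
  expect_gte(tot_greedy / tot_opt, 0.95)
})

test_that("pair_reads consumes a feasible tally and caps at paired_count", {
  # unique feasible pairing
  p <- pair_reads(c(0L, 200L), c(100L, 300L),
                  tally_new(300L), paired_count = 2L)
  expect_equal(nrow(p$pairs), 1L)
  expect_equal(p$pairs$dist, 300L)
  expect_equal(length(p$singles), 0L)

  # two nested fragments, distances from truth: tally exactly consumed
  starts <- c(0L, 50L, 150L, 250L)
  ends <- c(100L, 150L, 250L, 350L)
  truth <- tally_new(c(350L, 200L))   # (0,250..350) and (50,150..250)
  p2 <- pair_reads(starts, ends, truth, paired_count = 4L)
  expect_equal(sort(p2$pairs$dist), sort(truth$value))
  expect_equal(length(p2$singles), 0L)

  # 3 reads, tally {d:1}, paired_count 2 -> 1 pair + 1 single
  p3 <- with_seed(5L, pair_reads(c(0L, 200L, 400L), c(100L, 300L, 500L),
                                 tally_new(300L), paired_count = 2L))
  expect_equal(nrow(p3$pairs), 1L)
  expect_equal(length(p3$singles), 1L)
})

test_that("second-pass pairing is random but seeded", {
  starts <- c(0L, 100L, 200L, 300L)
  ends <- starts + 50L
  # no tally entries match: everything falls to the random second pass
  p1 <- with_seed(3L, pair_reads(starts, ends, tally_new(7L), 4L))
  p2 <- with_seed(3L, pair_reads(starts, ends, tally_new(7L), 4L))
  expect_identical(p1, p2)
  expect_equal(nrow(p1$pairs), 2L)
})

test_that("expand_bundle reproduces uniform buckets and junctions", {
  # spliced + unspliced reads through a full compress/expand cycle
  a <- make_aln("chr1", list(
    blk(0, 100), blk(0, 100),
    blk(50, 150, 400, 450), blk(50, 150, 400, 450),
    blk(420, 520)
  ))
  a <- a[order(a$start), ]
  chroms <- data.frame(name = "chr1", length = 10000L)
  build <- compress_alignments(a, chroms, seed = 1L)
  tf <- withr::local_tempfile(fileext = ".cvp")
  coverpress:::serialize_archive(build, tf)
  arc <- open_archive(tf)
  out <- expand_bundle(arc, 1L, seed = 1L)
  key <- function(x) sort(vapply(seq_len(nrow(x)), function(i) {
    paste(x$start[i], paste(x$blocks[[i]], collapse = ","))
  }, ""))
  expect_equal(key(out), key(a))
  # every recovered read crossing the junction carries it
  spliced <- out[vapply(out$blocks, nrow, integer(1)) > 1L, ]
  expect_equal(nrow(spliced), 2L)
  expect_equal(spliced$blocks[[1L]][, "end"][1L], 150L)
  expect_equal(spliced$blocks[[1L]][, "start"][2L], 400L)
})

test_that("expansion is deterministic given the seed", {
  txome <- gen_transcriptome(n_genes = 6L, seed = 8L)
  tf <- withr::local_tempfile(fileext = ".sam")
  gen_reads(txome, n_reads = 800L, paired = TRUE, sam_out = tf, seed = 2L)
  cvp <- withr::local_tempfile(fileext = ".cvp")
  compress_sam(tf, cvp, seed = 3L)
  s1 <- withr::local_tempfile(fileext = ".sam")
  s2 <- withr::local_tempfile(fileext = ".sam")
  decompress_archive(cvp, s1, seed = 9L)
  decompress_archive(cvp, s2, seed = 9L)
  expect_identical(readLines(s1), readLines(s2))
})

test_that("cross-bundle pairs survive the unbundled round trip", {
  a <- make_aln("chr1", list(blk(100, 200), blk(5000, 5100)),
                paired = c(TRUE, TRUE), pair_id = c(1L, 1L),
                tlen = c(5000L, -5000L), mate_start = c(5000L, 100L))
  chroms <- data.frame(name = "chr1", length = 10000L)
  build <- compress_alignments(a, chroms, seed = 1L)
  expect_equal(length(build$unbundled), 1L)
  tf <- withr::local_tempfile(fileext = ".cvp")
  coverpress:::serialize_archive(build, tf)
  arc <- open_archive(tf)
  out <- expand_unbundled(arc, seed = 1L)
  expect_equal(nrow(out), 2L)
  expect_equal(sort(out$start), c(100L, 5000L))
  expect_true(all(out$paired))
  expect_equal(out$mate_start[order(out$start)], c(5000L, 100L))
  expect_equal(sort(out$tlen), c(-5000L, 5000L))
  # empty section expands to nothing
  build2 <- compress_alignments(make_aln("chr1", list(blk(0, 50))),
                                chroms, seed = 1L)
  coverpress:::serialize_archive(build2, tf)
  out2 <- expand_unbundled(open_archive(tf), seed = 1L)
  expect_equal(nrow(out2), 0L)
})

test_that("cross-chromosome pairs emit mutual mate references", {
  a <- coverpress:::alignment_table(
    chrom = c("chr1", "chr2"), start = c(100L, 300L),
    blocks = list(blk(100, 200), blk(300, 400)),
    length = c(100L, 100L), strand = c("*", "*"), nh = c(1L, 1L),
    paired = c(TRUE, TRUE), mate_chrom = c("chr2", "chr1"),
    mate_start = c(300L, 100L), tlen = c(0L, 0L), pair_id = c(1L, 1L)
  )
  chroms <- data.frame(name = c("chr1", "chr2"),
                       length = c(10000L, 10000L))
  build <- compress_alignments(a, chroms, seed = 1L)
  expect_equal(length(build$unbundled), 1L)
  tf <- withr::local_tempfile(fileext = ".cvp")
  coverpress:::serialize_archive(build, tf)
  out <- expand_unbundled(open_archive(tf), seed = 1L)
  expect_equal(sort(out$chrom), c("chr1", "chr2"))
  expect_equal(out$mate_chrom[out$chrom == "chr1"], "chr2")
  expect_equal(out$tlen, c(0L, 0L))
})
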