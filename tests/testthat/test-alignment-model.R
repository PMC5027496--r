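test_that("parse_cigar splits blocks at N only and folds D", {
  expect_equal(parse_cigar("100M", 0L),
               list(blocks = blk(0, 100), length = 100L))
  expect_equal(parse_cigar("50M200N50M", 1000L),
               list(blocks = blk(1000, 1050, 1250, 1300), length = 100L))
  expect_equal(parse_cigar("10M5D10M", 0L),
               list(blocks = blk(0, 25), length = 25L))
  # soft clips and insertions are flattened away
  expect_equal(parse_cigar("5S10M2I10M3S", 7L)$blocks, blk(7, 27))
})

test_that("parse_cigar agrees with the GenomicAlignments oracle", {
  cigars <- c("10M5D10M", "5S20M", "10M100N10M3D2M", "3M2I3M10N4M",
              "8M1D2M5N6M", "25M")
  pos <- c(0L, 11L, 100L, 5L, 60L, 3L)
  ranges <- GenomicAlignments::extractAlignmentRangesOnReference(
    cigars, pos = pos + 1L, drop.D.ranges = FALSE
  )
  for (i in seq_along(cigars)) {
    got <- parse_cigar(cigars[i], pos[i])$blocks
    r <- ranges[[i]]
    expect_equal(unname(got[, "start"]),
                 as.integer(BiocGenerics::start(r)) - 1L,
                 info = cigars[i])
    expect_equal(unname(got[, "end"]), as.integer(BiocGenerics::end(r)),
                 info = cigars[i])
  }
})

test_that("malformed CIGARs raise errors naming the offending token", {
  expect_error(parse_cigar("10M5Q10M", 0L), "Q")
  expect_error(parse_cigar("*", 0L), "malformed")
  expect_error(parse_cigar("100N", 0L), "no aligned bases")
})

test_that("blocks_to_cigar inverts parse_cigar on M/N shapes", {
  set.seed(11)
  for (rep in 1:25) {
    nb <- sample(1:4, 1L)
    widths <- sample(10:120, nb, replace = TRUE)
    gaps <- if (nb > 1L) sample(50:500, nb - 1L, replace = TRUE) else NULL
    starts <- 100L + c(0L, cumsum(widths[-nb] + gaps))
    b <- cbind(start = starts, end = starts + widths)
    cg <- blocks_to_cigar(b)
    back <- parse_cigar(cg, 100L)
    expect_equal(unname(back$blocks[, 1L]), unname(b[, 1L]))
    expect_equal(unname(back$blocks[, 2L]), unname(b[, 2L]))
    expect_equal(back$length, sum(widths))
  }
})

test_that("read_sam skips unaligned records and applies tag defaults", {
  sam <- c(
    "@HD\tVN:1.6\tSO:coordinate",
    "@SQ\tSN:chr1\tLN:10000",
    "r1\t0\tchr1\t101\t50\t50M\t*\t0\t0\t*\t*\tNH:i:3\tXS:A:+",
    "r2\t4\t*\t0\t0\t*\t*\t0\t0\t*\t*",
    "r3\t0\tchr1\t201\t50\t30M10N20M\t*\t0\t0\t*\t*",
    "r4\t0\tchr1\t301\t50\t50M\t*\t0\t0\t*\t*"
  )
  tf <- withr::local_tempfile(fileext = ".sam")
  writeLines(sam, tf)
  res <- read_sam(tf)
  expect_equal(res$chroms, data.frame(name = "chr1", length = 10000L))
  a <- res$alignments
  expect_equal(nrow(a), 3L)           # unaligned r2 skipped
  expect_equal(a$start, c(100L, 200L, 300L))
  expect_equal(a$nh, c(3L, 1L, 1L))   # NH default 1
  expect_equal(a$strand, c("+", "*", "*"))
  expect_equal(a$blocks[[2L]], blk(200, 230, 240, 260))
})

test_that("orphans and mateless ends are demoted to unpaired reads", {
  sam <- c(
    "@SQ\tSN:chr1\tLN:10000",
    # mate-unmapped flag set
    "p1\t73\tchr1\t101\t50\t50M\t*\t0\t0\t*\t*",
    # paired flags but the mate record never appears
    "p2\t65\tchr1\t201\t50\t50M\t=\t900\t799\t*\t*",
    # intact pair
    "p3\t67\tchr1\t301\t50\t50M\t=\t501\t250\t*\t*",
    "p3\t131\tchr1\t501\t50\t50M\t=\t301\t-250\t*\t*"
  )
  tf <- withr::local_tempfile(fileext = ".sam")
  writeLines(sam, tf)
  a <- read_sam(tf)$alignments
  expect_equal(a$paired, c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(a$pair_id[3L], a$pair_id[4L])
  expect_equal(a$tlen, c(0L, 0L, 250L, -250L))
})

test_that("unsorted input is rejected with the offending record", {
  sam <- c(
    "@SQ\tSN:chr1\tLN:10000",
    "r1\t0\tchr1\t500\t50\t50M\t*\t0\t0\t*\t*",
    "r2\t0\tchr1\t100\t50\t50M\t*\t0\t0\t*\t*"
  )
  tf <- withr::local_tempfile(fileext = ".sam")
  writeLines(sam, tf)
  expect_error(read_sam(tf), "not coordinate-sorted.*record 2")
  sam2 <- c(
    "@SQ\tSN:chr1\tLN:10000", "@SQ\tSN:chr2\tLN:10000",
    "r1\t0\tchr1\t100\t50\t50M\t*\t0\t0\t*\t*",
    "r2\t0\tchr2\t100\t50\t50M\t*\t0\t0\t*\t*",
    "r3\t0\tchr1\t200\t50\t50M\t*\t0\t0\t*\t*"
  )
  writeLines(sam2, tf)
  expect_error(read_sam(tf), "previously seen chromosome")
})

test_that("write_sam emits valid coordinate-sorted SAM that round-trips", {
  a <- make_aln("chr1", list(blk(0, 100), blk(500, 550, 800, 850)))
  a$strand <- c("*", "+")
  chroms <- data.frame(name = "chr1", length = 5000L)
  tf <- withr::local_tempfile(fileext = ".sam")
  write_sam(a, chroms, tf)
  lines <- readLines(tf)
  body <- lines[!startsWith(lines, "@")]
  expect_equal(length(body), 2L)
  f <- strsplit(body[1L], "\t")[[1L]]
  expect_equal(f[4L], "1")            # 1-based POS
  expect_equal(f[6L], "100M")
  f2 <- strsplit(body[2L], "\t")[[1L]]
  expect_equal(f2[6L], "50M250N50M")  # one N op of the junction length
  back <- read_sam(tf)$alignments
  expect_equal(back$start, a$start)
  expect_equal(back$blocks, a$blocks)
  expect_equal(back$strand, a$strand)
})

test_that("write_sam emits symmetric pairs and rejects broken ones", {
  a <- make_aln("chr1", list(blk(100, 200), blk(400, 500)),
                paired = c(TRUE, TRUE), pair_id = c(1L, 1L),
                tlen = c(400L, -400L), mate_start = c(400L, 100L))
  chroms <- data.frame(name = "chr1", length = 5000L)
  tf <- withr::local_tempfile(fileext = ".sam")
  write_sam(a, chroms, tf)
  body <- grep("^@", readLines(tf), value = TRUE, invert = TRUE)
  f1 <- strsplit(body[1L], "\t")[[1L]]
  f2 <- strsplit(body[2L], "\t")[[1L]]
  expect_equal(f1[1L], f2[1L])                   # shared name
  expect_true(bitwAnd(as.integer(f1[2L]), 1L) == 1L)
  expect_equal(as.integer(f1[9L]), 400L)
  expect_equal(as.integer(f2[9L]), -400L)
  bad <- a
  bad$mate_start <- c(NA_integer_, NA_integer_)
  expect_error(write_sam(bad, chroms, tf), "incomplete mate fields")
})

test_that("BAM input is read through the binary adapter", {
  a <- make_aln("chr1", list(blk(0, 100), blk(300, 400)))
  chroms <- data.frame(name = "chr1", length = 5000L)
  tf <- withr::local_tempfile(fileext = ".sam")
  write_sam(a, chroms, tf)
  bam <- Rsamtools::asBam(tf, withr::local_tempfile(), overwrite = TRUE)
  back <- read_sam(bam)$alignments
  expect_equal(back$start, a$start)
  expect_equal(back$length, a$length)
})

test_that("read_sam preserves input order among kept records", {
  txome <- gen_transcriptome(n_genes = 6L, seed = 21L)
  tf <- withr::local_tempfile(fileext = ".sam")
  res <- gen_reads(txome, n_reads = 400L, sam_out = tf, seed = 3L)
  a <- read_sam(tf)$alignments
  for (chrom in unique(a$chrom)) {
    expect_false(is.unsorted(a$start[a$chrom == chrom]))
  }
  expect_equal(a$start, res$alignments$start)
})
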