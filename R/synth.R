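# Synthetic spliced-alignment generator. Produces a small transcriptome
# (non-overlapping genes, gaps > 50 bases so bundle boundaries are
# predictable), samples uniform- or mixed-length unpaired or paired reads
# from transcript coordinates, projects them to genomic blocks (N CIGARs
# across introns), and writes coordinate-sorted SAM plus exact truth tables
# for the test suite.

#' Generate a synthetic transcriptome
#'
#' Genes are placed left to right with inter-gene gaps larger than the
#' bundling threshold, one transcript per gene.
#'
#' @param n_genes number of genes.
#' @param exons_per_gene integer range `c(lo, hi)`.
#' @param exon_length,intron_length,gene_gap integer ranges sampled
#'   uniformly.
#' @param chroms chromosome names; genes are distributed round-robin.
#' @param seed RNG seed.
#' @return list with `transcripts` (list of [transcript()] objects) and
#'   `chroms` (data.frame `name`, `length`).
#' @export
gen_transcriptome <- function(n_genes = 20L, exons_per_gene = c(1L, 4L),
                              exon_length = c(150L, 400L),
                              intron_length = c(60L, 300L),
                              gene_gap = c(100L, 1000L),
                              chroms = c("chr1", "chr2"), seed = 1L) {
  stopifnot(n_genes >= 1L, exons_per_gene[1L] >= 1L, gene_gap[1L] > 50L)
  pick <- function(lo, hi, n = 1L) {
    if (lo == hi) rep.int(as.integer(lo), n)
    else sample(seq.int(lo, hi), n, replace = TRUE)
  }
  with_seed(seed, {
    cursor <- stats::setNames(rep(1000L, length(chroms)), chroms)
    txs <- vector("list", n_genes)
    for (g in seq_len(n_genes)) {
      chrom <- chroms[(g - 1L) %% length(chroms) + 1L]
      nex <- pick(exons_per_gene[1L], exons_per_gene[2L])
      elen <- pick(exon_length[1L], exon_length[2L], nex)
      ilen <- if (nex > 1L) {
        pick(intron_length[1L], intron_length[2L], nex - 1L)
      } else integer(0)
      s <- cursor[[chrom]]
      starts <- s + c(0L, cumsum(elen[-nex] + ilen))
      ends <- starts + elen
      txs[[g]] <- transcript(
        id = sprintf("tx%03d", g), chrom = chrom,
        strand = sample(c("+", "-"), 1L),
        exons = cbind(starts, ends), coverage = 1
      )
      gap <- pick(gene_gap[1L], gene_gap[2L])
      cursor[[chrom]] <- ends[nex] + gap
    }
    list(
      transcripts = txs,
      chroms = data.frame(
        name = chroms,
        length = as.integer(cursor + 1000L),
        stringsAsFactors = FALSE
      )
    )
  })
}

#' Write transcripts as GTF
#'
#' @param transcripts list of [transcript()] objects.
#' @param path output file.
#' @export
write_gtf <- function(transcripts, path) {
  lines <- unlist(lapply(transcripts, function(t) {
    ex <- t$exons
    attr_ <- sprintf('gene_id "%s"; transcript_id "%s";', t$id, t$id)
    c(
      sprintf("%s\tsynth\ttranscript\t%d\t%d\t.\t%s\t.\t%s",
              t$chrom, ex[1L, 1L] + 1L, ex[nrow(ex), 2L], t$strand, attr_),
      sprintf("%s\tsynth\texon\t%d\t%d\t.\t%s\t.\t%s",
              t$chrom, ex[, 1L] + 1L, ex[, 2L], t$strand, attr_)
    )
  }), use.names = FALSE)
  writeLines(lines, path)
  invisible(path)
}

# project a transcript-coordinate interval [s, s + l) to genomic blocks
project_to_genome <- function(tx, s, l) {
  ex <- tx$exons
  elen <- ex[, 2L] - ex[, 1L]
  offs <- c(0L, cumsum(elen))
  bs <- integer(0)
  be <- integer(0)
  lo <- s
  hi <- s + l
  for (k in seq_len(nrow(ex))) {
    a <- max(lo, offs[k])
    b <- min(hi, offs[k + 1L])
    if (a < b) {
      bs <- c(bs, ex[k, 1L] + (a - offs[k]))
      be <- c(be, ex[k, 1L] + (b - offs[k]))
    }
  }
  cbind(start = as.integer(bs), end = as.integer(be))
}

tx_length <- function(tx) sum(tx$exons[, 2L] - tx$exons[, 1L])

# batch projection: group reads by transcript, fast path for reads that fit
# inside one exon
project_grouped <- function(txs, ti, s, l) {
  n <- length(ti)
  blocks <- vector("list", n)
  for (t in unique(ti)) {
    idx <- which(ti == t)
    tx <- txs[[t]]
    ex <- tx$exons
    offs <- c(0L, cumsum(ex[, 2L] - ex[, 1L]))
    k1 <- findInterval(s[idx], offs)
    k2 <- findInterval(s[idx] + l[idx] - 1L, offs)
    onex <- k1 == k2
    for (j in idx[onex]) {
      k <- findInterval(s[j], offs)
      gs <- ex[k, 1L] + (s[j] - offs[k])
      blocks[[j]] <- cbind(start = as.integer(gs),
                           end = as.integer(gs + l[j]))
    }
    for (j in idx[!onex]) {
      blocks[[j]] <- project_to_genome(tx, s[j], l[j])
    }
  }
  blocks
}

#' Generate synthetic reads as SAM plus truth tables
#'
#' Reads are sampled from transcript coordinates (expression weights drawn
#' log-normally) and projected to genomic blocks. Spliced reads carry XS:A
#' from the gene strand. Paired fragments draw transcript-space lengths from
#' a truncated normal; TLEN records the genomic outer distance after
#' projection. Optional rates inject multi-mappers (NH:i:2, duplicate
#' placement), orphans (mate-unmapped flag), discordant-strand pairs, and
#' distant / cross-chromosome pairs.
#'
#' @param txome from [gen_transcriptome()].
#' @param n_reads number of ends (a pair counts as two).
#' @param read_length integer vector; each read's length is drawn uniformly
#'   from it (a scalar gives uniform-length reads).
#' @param paired generate paired-end fragments.
#' @param tlen_mean,tlen_sd transcript-space fragment length distribution.
#' @param nh_rate fraction of unpaired reads duplicated at a second location
#'   with NH:i:2.
#' @param orphan_rate fraction of fragments whose right end is unmapped.
#' @param discordant_rate fraction of fragments with opposite XS strands.
#' @param distant_rate,cross_rate fraction of fragments whose ends land on
#'   two different genes of the same / of different chromosomes.
#' @param sam_out path for the SAM file (`NULL` for none).
#' @param seed RNG seed.
#' @return list: `alignments` (truth alignment table, as [read_sam()] would
#'   return it), `chroms`, `tlen_tally` (same-chromosome pairs), `sam`
#'   (path, if written).
#' @export
gen_reads <- function(txome, n_reads = 2000L, read_length = 100L,
                      paired = FALSE, tlen_mean = 250, tlen_sd = 30,
                      nh_rate = 0, orphan_rate = 0, discordant_rate = 0,
                      distant_rate = 0, cross_rate = 0,
                      sam_out = NULL, seed = 1L) {
  txs <- txome$transcripts
  txlen <- vapply(txs, tx_length, numeric(1))
  if (any(txlen < max(read_length))) {
    stop("read longer than its transcript: shrink read_length or grow exons")
  }
  rec <- with_seed(seed, {
    w <- stats::rlnorm(length(txs)) * txlen
    if (paired) {
      gen_paired_records(txs, txlen, w, n_reads, read_length, tlen_mean,
                         tlen_sd, orphan_rate, discordant_rate,
                         distant_rate, cross_rate)
    } else {
      gen_unpaired_records(txs, txlen, w, n_reads, read_length, nh_rate)
    }
  })
  chrom_order <- match(rec$chrom, txome$chroms$name)
  ord <- order(chrom_order, rec$pos)
  rec <- lapply(rec, function(col) col[ord])
  out <- list(
    alignments = records_to_table(rec),
    chroms = txome$chroms,
    tlen_tally = tally_new(abs(rec$tlen[rec$is_paired & !rec$orphan &
                                        rec$tlen > 0L &
                                        (rec$mchrom == "=" |
                                           rec$mchrom == rec$chrom)]))
  )
  if (!is.null(sam_out)) {
    write_record_sam(rec, txome$chroms, sam_out)
    out$sam <- sam_out
  }
  out
}

# preallocated record builder (naive c() growth is quadratic)
new_records <- function(n) {
  env <- new.env(parent = emptyenv())
  env$qname <- character(n)
  env$flag <- integer(n)
  env$chrom <- character(n)
  env$pos <- integer(n)
  env$cigar <- character(n)
  env$mchrom <- character(n)
  env$mpos <- integer(n)
  env$tlen <- integer(n)
  env$nh <- integer(n)
  env$xs <- character(n)
  env$is_paired <- logical(n)
  env$orphan <- logical(n)
  env$blocks <- vector("list", n)
  env$k <- 0L
  env
}

push_record <- function(rec, qname, flag, chrom, pos, cigar, mchrom, mpos,
                        tlen, nh, xs, is_paired, orphan, blocks) {
  k <- rec$k + 1L
  rec$qname[k] <- qname
  rec$flag[k] <- flag
  rec$chrom[k] <- chrom
  rec$pos[k] <- pos
  rec$cigar[k] <- cigar
  rec$mchrom[k] <- mchrom
  rec$mpos[k] <- mpos
  rec$tlen[k] <- tlen
  rec$nh[k] <- nh
  rec$xs[k] <- xs
  rec$is_paired[k] <- is_paired
  rec$orphan[k] <- orphan
  rec$blocks[[k]] <- blocks
  rec$k <- k
  rec
}

finish_records <- function(rec) {
  k <- rec$k
  list(qname = rec$qname[seq_len(k)], flag = rec$flag[seq_len(k)],
       chrom = rec$chrom[seq_len(k)], pos = rec$pos[seq_len(k)],
       cigar = rec$cigar[seq_len(k)], mchrom = rec$mchrom[seq_len(k)],
       mpos = rec$mpos[seq_len(k)], tlen = rec$tlen[seq_len(k)],
       nh = rec$nh[seq_len(k)], xs = rec$xs[seq_len(k)],
       is_paired = rec$is_paired[seq_len(k)],
       orphan = rec$orphan[seq_len(k)],
       blocks = rec$blocks[seq_len(k)])
}

sample_end <- function(txs, txlen, w, rl, ti = NULL) {
  if (is.null(ti)) ti <- sample.int(length(txs), 1L, prob = w)
  tx <- txs[[ti]]
  s <- sample.int(txlen[ti] - rl + 1L, 1L) - 1L
  blocks <- project_to_genome(tx, s, rl)
  list(ti = ti, tx = tx, blocks = blocks,
       spliced = nrow(blocks) > 1L,
       gstart = blocks[1L, 1L], gend = blocks[nrow(blocks), 2L],
       cigar = blocks_to_cigar(blocks))
}

gen_unpaired_records <- function(txs, txlen, w, n_reads, read_length,
                                 nh_rate) {
  # decide primary reads and multi-mapper duplicates up front, then draw
  # everything in bulk
  is_dup <- logical(n_reads)
  if (nh_rate > 0) {
    i <- 1L
    while (i < n_reads) {
      if (stats::runif(1) < nh_rate) {
        is_dup[i + 1L] <- TRUE
        i <- i + 2L
      } else i <- i + 1L
    }
  }
  n <- n_reads
  rl <- if (length(read_length) > 1L) {
    sample(read_length, n, replace = TRUE)
  } else rep.int(read_length, n)
  # a duplicate placement reuses the primary's read length
  if (any(is_dup)) rl[which(is_dup)] <- rl[which(is_dup) - 1L]
  ti <- sample.int(length(txs), n, replace = TRUE, prob = w)
  s <- floor(stats::runif(n) * (txlen[ti] - rl + 1))
  blocks <- project_grouped(txs, ti, s, rl)
  nbl <- vapply(blocks, nrow, integer(1))
  strands <- vapply(txs, `[[`, "", "strand")
  chroms <- vapply(txs, `[[`, "", "chrom")
  primary <- which(!is_dup)
  qn <- character(n)
  qn[primary] <- sprintf("s%d", primary)
  qn[is_dup] <- qn[which(is_dup) - 1L]
  nh <- rep.int(1L, n)
  nh[is_dup] <- 2L
  nh[which(is_dup) - 1L] <- 2L
  cig <- character(n)
  one <- nbl == 1L
  cig[one] <- paste0(rl[one], "M")
  cig[!one] <- vapply(blocks[!one], blocks_to_cigar, "")
  list(
    qname = qn,
    flag = ifelse(is_dup, 256L, 0L),
    chrom = chroms[ti],
    pos = vapply(blocks, function(b) b[1L, 1L], integer(1)),
    cigar = cig,
    mchrom = rep("*", n), mpos = rep.int(0L, n),
    tlen = rep.int(0L, n), nh = nh,
    xs = ifelse(nbl > 1L, strands[ti], "*"),
    is_paired = rep.int(FALSE, n), orphan = rep.int(FALSE, n),
    blocks = blocks
  )
}

gen_paired_records <- function(txs, txlen, w, n_reads, read_length,
                               tlen_mean, tlen_sd, orphan_rate,
                               discordant_rate, distant_rate, cross_rate) {
  rec <- new_records(n_reads + 2L)
  n_frag <- n_reads %/% 2L
  chroms_of <- vapply(txs, `[[`, "", "chrom")
  for (fi in seq_len(n_frag)) {
    qn <- sprintf("p%d", fi)
    rl <- if (length(read_length) > 1L) sample(read_length, 1L)
          else read_length
    u <- stats::runif(1)
    if (u < cross_rate + distant_rate && length(txs) > 1L) {
      want_cross <- u < cross_rate
      ti1 <- sample.int(length(txs), 1L, prob = w)
      ok <- if (want_cross) which(chroms_of != chroms_of[ti1])
            else which(chroms_of == chroms_of[ti1] & seq_along(txs) != ti1)
      if (length(ok)) {
        ti2 <- if (length(ok) == 1L) ok else sample(ok, 1L)
        e1 <- sample_end(txs, txlen, w, rl, ti1)
        e2 <- sample_end(txs, txlen, w, rl, ti2)
        if (e1$tx$chrom > e2$tx$chrom ||
            (e1$tx$chrom == e2$tx$chrom && e1$gstart > e2$gstart)) {
          tmp <- e1; e1 <- e2; e2 <- tmp
        }
        same <- e1$tx$chrom == e2$tx$chrom
        d <- if (same) e2$gend - e1$gstart else 0L
        xs1 <- if (e1$spliced) e1$tx$strand else "*"
        xs2 <- if (e2$spliced) e2$tx$strand else "*"
        rec <- push_record(rec, qn, 1L + 64L, e1$tx$chrom, e1$gstart,
                           e1$cigar, if (same) "=" else e2$tx$chrom,
                           e2$gstart, d, 1L, xs1, TRUE, FALSE, e1$blocks)
        rec <- push_record(rec, qn, 1L + 128L, e2$tx$chrom, e2$gstart,
                           e2$cigar, if (same) "=" else e1$tx$chrom,
                           e1$gstart, -d, 1L, xs2, TRUE, FALSE, e2$blocks)
        next
      }
    }
    # ordinary fragment on one transcript
    ti <- sample.int(length(txs), 1L, prob = w)
    tx <- txs[[ti]]
    flen <- round(stats::rnorm(1, tlen_mean, tlen_sd))
    flen <- max(rl, min(txlen[ti], flen))
    fs <- sample.int(txlen[ti] - flen + 1L, 1L) - 1L
    b1 <- project_to_genome(tx, fs, rl)
    b2 <- project_to_genome(tx, fs + flen - rl, rl)
    g1 <- b1[1L, 1L]
    g2 <- b2[1L, 1L]
    e2end <- b2[nrow(b2), 2L]
    d <- e2end - g1
    orphan <- stats::runif(1) < orphan_rate
    disc <- !orphan && stats::runif(1) < discordant_rate
    xs1 <- if (nrow(b1) > 1L) tx$strand else "*"
    xs2 <- if (nrow(b2) > 1L) tx$strand else "*"
    if (disc) {
      xs1 <- tx$strand
      xs2 <- if (tx$strand == "+") "-" else "+"
    }
    if (orphan) {
      rec <- push_record(rec, qn, 1L + 8L + 64L, tx$chrom, g1,
                         blocks_to_cigar(b1), "*", 0L, 0L, 1L, xs1,
                         TRUE, TRUE, b1)
    } else {
      rec <- push_record(rec, qn, 1L + 64L, tx$chrom, g1,
                         blocks_to_cigar(b1), "=", g2, d, 1L, xs1,
                         TRUE, FALSE, b1)
      rec <- push_record(rec, qn, 1L + 128L, tx$chrom, g2,
                         blocks_to_cigar(b2), "=", g1, -d, 1L, xs2,
                         TRUE, FALSE, b2)
    }
  }
  finish_records(rec)
}

write_record_sam <- function(rec, chroms, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "@HD\tVN:1.6\tSO:coordinate",
    sprintf("@SQ\tSN:%s\tLN:%d", chroms$name, chroms$length)
  ), con)
  if (length(rec$qname)) {
    tags <- sprintf("NH:i:%d", rec$nh)
    has_xs <- rec$xs != "*"
    tags[has_xs] <- paste0(tags[has_xs], "\tXS:A:", rec$xs[has_xs])
    mpos1 <- ifelse(rec$mchrom == "*", 0L, rec$mpos + 1L)
    writeLines(sprintf("%s\t%d\t%s\t%d\t50\t%s\t%s\t%d\t%d\t*\t*\t%s",
                       rec$qname, rec$flag, rec$chrom, rec$pos + 1L,
                       rec$cigar, rec$mchrom, mpos1, rec$tlen, tags), con)
  }
  invisible(path)
}

# truth table in the same shape read_sam() produces (orphans demoted)
records_to_table <- function(rec) {
  n <- length(rec$qname)
  if (n == 0L) return(empty_alignment_table())
  lens <- vapply(rec$blocks, function(b) sum(b[, 2L] - b[, 1L]), integer(1))
  eff_paired <- rec$is_paired & !rec$orphan
  pair_id <- rep(NA_integer_, n)
  if (any(eff_paired)) {
    pair_id[eff_paired] <- match(rec$qname[eff_paired],
                                 unique(rec$qname[eff_paired]))
  }
  alignment_table(
    chrom = rec$chrom, start = rec$pos, blocks = rec$blocks,
    length = lens, strand = rec$xs, nh = rec$nh,
    paired = eff_paired,
    mate_chrom = ifelse(eff_paired,
                        ifelse(rec$mchrom == "=", rec$chrom, rec$mchrom),
                        NA_character_),
    mate_start = ifelse(eff_paired, rec$mpos, NA_integer_),
    tlen = ifelse(eff_paired, rec$tlen, 0L),
    pair_id = pair_id
  )
}
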