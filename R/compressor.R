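# Bundle -> buckets. A bundle's span is cut at every splice site observed in
# its alignments, yielding "partitions". Each alignment maps to a bucket
# keyed by (subset of partitions its blocks touch, NH value, strand tag);
# each bucket stores one coverage vector over the concatenation of its
# spanned partitions plus a read-length tally. Genomic outer distance (TLEN)
# tallies are kept per bucket, one entry per pair, on the leftmost end's
# bucket.

#' Cut a bundle span into partitions at observed splice sites
#'
#' @param blocks_list list of block matrices of the bundle's alignments.
#' @param span_start,span_end bundle span (0-based half-open).
#' @return data.frame `start`, `end`: consecutive intervals tiling the span,
#'   with boundaries at every distinct junction donor/acceptor.
#' @export
partition_bundle <- function(blocks_list, span_start, span_end) {
  cuts <- numeric(0)
  for (b in blocks_list) {
    if (nrow(b) > 1L) {
      j <- blocks_junctions(b)
      cuts <- c(cuts, j[, "donor"], j[, "acceptor"])
    }
  }
  cuts <- sort(unique(cuts))
  cuts <- cuts[cuts > span_start & cuts < span_end]
  bounds <- c(span_start, cuts, span_end)
  data.frame(
    start = as.integer(bounds[-length(bounds)]),
    end = as.integer(bounds[-1L])
  )
}

# Spanned partition ordinals for one block matrix. Partition boundaries
# include every junction boundary, so each block maps to a contiguous
# ordinal range; introns between blocks are skipped.
spanned_partitions <- function(blocks, pstart) {
  first <- findInterval(blocks[, 1L], pstart)
  last <- findInterval(blocks[, 2L] - 1L, pstart)
  if (any(first < 1L)) stop("alignment block outside all partitions")
  sort(unique(unlist(
    mapply(seq.int, first, last, SIMPLIFY = FALSE), use.names = FALSE
  )))
}

#' Assign an alignment to its bucket key
#'
#' @param blocks block matrix of the alignment.
#' @param partitions partition table from [partition_bundle()].
#' @param nh,strand NH value and strand tag of the alignment.
#' @return list `spanned` (ordinals), `nh`, `strand`.
#' @export
assign_bucket <- function(blocks, partitions, nh = 1L, strand = "*") {
  if (blocks[1L, 1L] < partitions$start[1L] ||
      blocks[nrow(blocks), 2L] > partitions$end[nrow(partitions)]) {
    stop("alignment block outside all partitions")
  }
  list(spanned = spanned_partitions(blocks, partitions$start),
       nh = as.integer(nh), strand = strand)
}

strand_code <- function(strand) {
  match(strand, c("*", "+", "-")) - 1L
}
strand_decode <- function(code) {
  c("*", "+", "-")[code + 1L]
}

#' Build the buckets of one bundle
#'
#' Groups alignments by bucket key, computes each bucket's coverage vector
#' over the concatenated spanned partitions, tallies read lengths, counts
#' paired ends, and tallies |TLEN| once per same-bundle pair (on the bucket
#' of the leftmost end). Buckets are ordered lexicographically by
#' (spanned subset, strand, nh).
#'
#' @param alignments alignment table of one bundle.
#' @param partitions partition table from [partition_bundle()].
#' @return list of buckets; each is a list with `spanned`, `nh`, `strand`,
#'   `coverage` (`coverage_rle`), `length_tally`, `paired_count`,
#'   `tlen_tally`.
#' @export
build_buckets <- function(alignments, partitions) {
  a <- alignments
  n <- nrow(a)
  if (n == 0L) return(list())
  pstart <- partitions$start
  plen <- partitions$end - partitions$start

  # flatten all blocks; each block covers a contiguous partition range
  nb1 <- vapply(a$blocks, nrow, integer(1))
  bl <- do.call(rbind, a$blocks)
  owner <- rep.int(seq_len(n), nb1)
  first <- findInterval(bl[, 1L], pstart)
  last <- findInterval(bl[, 2L] - 1L, pstart)
  if (any(first < 1L) ||
      any(bl[, 2L] > partitions$end[nrow(partitions)])) {
    stop("alignment block outside all partitions")
  }
  # spanned ordinals per alignment (block ranges are disjoint & ascending)
  rlens <- last - first + 1L
  sp_all <- sequence(rlens) - 1L + rep.int(first, rlens)
  ofac <- factor(owner, levels = seq_len(n))
  span_list <- split(sp_all, factor(rep.int(owner, rlens),
                                    levels = seq_len(n)))

  scode <- strand_code(a$strand)
  range_tok <- paste0(first, "-", last)
  keys <- paste(
    vapply(split(range_tok, ofac), paste, "", collapse = ","),
    scode, a$nh, sep = "|"
  )

  # tlen tally target bucket: leftmost end of each still-paired pair
  tlen_val <- rep(NA_integer_, n)
  if (any(a$paired)) {
    p <- which(a$paired)
    ordp <- p[order(a$pair_id[p], a$start[p], a$end[p])]
    firsts <- ordp[!duplicated(a$pair_id[ordp])]
    tlen_val[firsts] <- abs(a$tlen[firsts])
  }

  groups <- split(seq_len(n), keys)
  # deterministic bucket order: (spanned subset, strand, nh) lexicographic
  sortkeys <- vapply(groups, function(g) {
    i0 <- g[1L]
    paste(paste(sprintf("%09d", span_list[[i0]]), collapse = ","),
          scode[i0], sprintf("%09d", a$nh[i0]), sep = "|")
  }, "")
  groups <- groups[order(sortkeys)]
  bucket_of_aln <- integer(n)
  for (g in seq_along(groups)) bucket_of_aln[groups[[g]]] <- g
  block_groups <- split(seq_along(owner), bucket_of_aln[owner])

  buckets <- vector("list", length(groups))
  for (g in seq_along(groups)) {
    rows <- groups[[g]]
    i0 <- rows[1L]
    spanned <- span_list[[i0]]
    offs <- c(0L, cumsum(plen[spanned]))
    total_len <- offs[length(offs)]
    bi <- block_groups[[as.character(g)]]
    # concat coordinates: affine per block, via the block's first partition
    cs <- offs[match(first[bi], spanned)] + (bl[bi, 1L] - pstart[first[bi]])
    ce <- cs + (bl[bi, 2L] - bl[bi, 1L])
    d <- tabulate(cs + 1L, total_len + 1L) - tabulate(ce + 1L, total_len + 1L)
    cov <- cumsum(d[seq_len(total_len)])
    buckets[[g]] <- list(
      spanned = spanned,
      nh = a$nh[i0],
      strand = a$strand[i0],
      coverage = rle_encode(cov),
      length_tally = tally_new(a$length[rows]),
      paired_count = sum(a$paired[rows]),
      tlen_tally = tally_new(tlen_val[rows][!is.na(tlen_val[rows])])
    )
  }
  buckets
}

# Map a bucket's spanned partition ordinals to genomic intervals and concat
# offsets; group genomically contiguous spanned partitions into segments.
bucket_geometry <- function(spanned, partitions) {
  gs <- partitions$start[spanned]
  ge <- partitions$end[spanned]
  segment_geometry(gs, ge)
}

# Same, but from explicit interval vectors (used by bundle-spanning buckets).
segment_geometry <- function(gs, ge) {
  len <- ge - gs
  offs <- c(0L, cumsum(len))
  k <- length(gs)
  newseg <- c(TRUE, gs[-1L] != ge[-k])
  seg <- cumsum(newseg)
  data.frame(
    gstart = as.integer(gs), gend = as.integer(ge),
    cstart = as.integer(offs[-length(offs)]),
    cend = as.integer(offs[-1L]),
    segment = as.integer(seg)
  )
}

# Map one concat-space interval back to genomic blocks, splitting only where
# consecutive spanned partitions are genomically discontiguous (introns).
concat_to_blocks <- function(cstart, cend, geom) {
  hit <- which(geom$cstart < cend & geom$cend > cstart)
  gs <- pmax(geom$gstart[hit], geom$gstart[hit] + (cstart - geom$cstart[hit]))
  ge <- pmin(geom$gend[hit], geom$gstart[hit] + (cend - geom$cstart[hit]))
  seg <- geom$segment[hit]
  keepnew <- c(TRUE, seg[-1L] != seg[-length(seg)])
  bs <- gs[keepnew]
  idx_end <- c(which(keepnew[-1L]), length(ge))
  be <- ge[idx_end]
  cbind(start = as.integer(bs), end = as.integer(be))
}
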