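# End-to-end compression and decompression.

#' Compress a coordinate-sorted SAM/BAM file into an archive
#'
#' Bundles the alignments, handles unbundled pairs, converts each bundle into
#' buckets of run-length-encoded coverage vectors plus read-length and
#' outer-distance tallies, and writes an indexed archive in which every
#' bundle (and every chunk of bundle-spanning buckets) is an independent
#' zlib-wrapped DEFLATE block. Read names, sequences, qualities and most
#' FLAG bits are discarded.
#'
#' @param sam_in input SAM (or BAM) file, coordinate-sorted.
#' @param archive_out output archive path (conventionally `.cvp`).
#' @param seed integer seed governing every stochastic step
#'   (discordant-strand harmonization here; random pairing at expansion).
#' @param preserve_nested keep intron-nested pairs paired instead of
#'   splitting them into unpaired reads.
#' @param split_discordant split discordant-strand pairs into unpaired reads
#'   instead of harmonizing one end's strand.
#' @param chunk_size bundle-spanning buckets per unbundled chunk.
#' @return invisibly, a summary list: bundle count, bucket count, unbundled
#'   bucket count, input and output byte sizes and the compression ratio.
#' @export
compress_sam <- function(sam_in, archive_out, seed = 1L,
                         preserve_nested = FALSE, split_discordant = FALSE,
                         chunk_size = UNBUNDLED_CHUNK_SIZE) {
  src <- read_sam(sam_in)
  build <- compress_alignments(src$alignments, src$chroms, seed = seed,
                               preserve_nested = preserve_nested,
                               split_discordant = split_discordant)
  serialize_archive(build, archive_out, chunk_size = chunk_size)
  nbk <- sum(vapply(build$payloads, function(p) length(p$buckets),
                    integer(1)))
  invisible(list(
    bundles = nrow(build$bundles),
    buckets = nbk,
    unbundled_buckets = length(build$unbundled),
    in_bytes = file.size(sam_in),
    out_bytes = file.size(archive_out),
    ratio = file.size(sam_in) / file.size(archive_out)
  ))
}

#' Compress an in-memory alignment table
#'
#' The in-memory half of [compress_sam()]; useful for testing individual
#' stages.
#'
#' @param alignments alignment table (coordinate-sorted).
#' @param chroms chromosome table (`name`, `length`).
#' @inheritParams compress_sam
#' @return archive build object accepted by [serialize_archive()].
#' @export
compress_alignments <- function(alignments, chroms, seed = 1L,
                                preserve_nested = FALSE,
                                split_discordant = FALSE) {
  bb <- build_bundles(alignments)
  hp <- with_seed(seed, {
    handle_special_pairs(alignments, bb$bundle_of,
                         preserve_nested = preserve_nested,
                         split_discordant = split_discordant)
  })
  a <- hp$alignments
  nb <- nrow(bb$bundles)
  payloads <- vector("list", nb)
  for (i in seq_len(nb)) {
    rows <- which(hp$bundle_of == i)
    if (length(rows) == 0L) {
      payloads[[i]] <- list(cuts = integer(0), buckets = list())
      next
    }
    sub <- a[rows, ]
    parts <- partition_bundle(sub$blocks, bb$bundles$start[i],
                              bb$bundles$end[i])
    payloads[[i]] <- list(
      cuts = parts$start[-1L],
      buckets = build_buckets(sub, parts)
    )
  }
  unbundled <- build_unbundled_buckets(hp$unbundled, chroms)
  list(chroms = chroms, bundles = bb$bundles, payloads = payloads,
       unbundled = unbundled)
}

# Group unbundled pairs into bundle-spanning buckets. Pairs share a bucket
# when both sides agree on (bundle, nh, strand, junction set); each side
# stores its spanned genomic partition intervals (its own span cut at its
# own splice sites, intron gaps dropped) so chunks expand independently of
# bundle blocks.
build_unbundled_buckets <- function(unb, chroms) {
  if (length(unb) == 0L) return(list())
  keyof <- function(u) {
    jl <- blocks_junctions(u$left$blocks[[1L]])
    jr <- blocks_junctions(u$right$blocks[[1L]])
    paste(u$bundle_left, u$bundle_right,
          u$left$nh, u$left$strand, u$right$nh, u$right$strand,
          paste(jl, collapse = ","), paste(jr, collapse = ","),
          sep = "|")
  }
  keys <- vapply(unb, keyof, "")
  groups <- split(unb, keys)
  groups <- groups[order(names(groups))]
  lapply(groups, function(g) {
    lrows <- lapply(g, `[[`, "left")
    rrows <- lapply(g, `[[`, "right")
    lside <- side_structure(lrows)
    rside <- side_structure(rrows)
    cov <- c(side_coverage(lrows, lside), side_coverage(rrows, rside))
    lens <- c(vapply(lrows, function(x) x$length, integer(1)),
              vapply(rrows, function(x) x$length, integer(1)))
    same_chrom <- g[[1L]]$left$chrom == g[[1L]]$right$chrom
    tl <- if (same_chrom) {
      vapply(g, function(u) abs(u$left$tlen), integer(1))
    } else integer(0)
    list(
      chrom_left = match(g[[1L]]$left$chrom, chroms$name),
      chrom_right = match(g[[1L]]$right$chrom, chroms$name),
      bundle_left = g[[1L]]$bundle_left,
      bundle_right = g[[1L]]$bundle_right,
      left = lside, right = rside,
      coverage = rle_encode(cov),
      length_tally = tally_new(lens),
      n_pairs = length(g),
      tlen_tally = tally_new(tl)
    )
  })
}

# Side geometry of an unbundled bucket: the member ends' common span cut at
# their (shared) junction set, keeping only non-intron intervals.
side_structure <- function(rows) {
  s <- min(vapply(rows, function(x) x$start, integer(1)))
  e <- max(vapply(rows, function(x) x$end, integer(1)))
  j <- blocks_junctions(rows[[1L]]$blocks[[1L]])
  cuts <- sort(unique(c(j[, "donor"], j[, "acceptor"])))
  cuts <- cuts[cuts > s & cuts < e]
  bounds <- c(s, cuts, e)
  ivs <- bounds[-length(bounds)]
  ive <- bounds[-1L]
  if (nrow(j)) {
    intronic <- vapply(seq_along(ivs), function(k) {
      any(ivs[k] >= j[, "donor"] & ive[k] <= j[, "acceptor"])
    }, logical(1))
    ivs <- ivs[!intronic]
    ive <- ive[!intronic]
  }
  list(iv_start = as.integer(ivs), iv_end = as.integer(ive),
       nh = rows[[1L]]$nh, strand = rows[[1L]]$strand)
}

side_coverage <- function(rows, side) {
  geom <- segment_geometry(side$iv_start, side$iv_end)
  total <- sum(geom$cend - geom$cstart)
  d <- numeric(total + 1L)
  for (x in rows) {
    b <- x$blocks[[1L]]
    for (k in seq_len(nrow(b))) {
      hit <- which(geom$gstart <= b[k, 1L] & geom$gend > b[k, 1L])
      cs <- geom$cstart[hit] + (b[k, 1L] - geom$gstart[hit])
      ce <- cs + (b[k, 2L] - b[k, 1L])
      d[cs + 1L] <- d[cs + 1L] + 1
      d[ce + 1L] <- d[ce + 1L] - 1
    }
  }
  as.integer(cumsum(d[seq_len(total)]))
}

#' Decompress an archive back to coordinate-sorted SAM
#'
#' Expands every bundle (read recovery, junction re-emission, pairing) and
#' the unbundled section, then writes SAM with synthetic read names.
#'
#' @param archive_in archive file.
#' @param sam_out output SAM path.
#' @param seed integer seed; with the same archive and seed the output is
#'   identical across runs.
#' @return invisibly, `sam_out`.
#' @export
decompress_archive <- function(archive_in, sam_out, seed = 1L) {
  arc <- open_archive(archive_in)
  tables <- lapply(seq_len(nrow(arc$bundles)), function(i) {
    expand_bundle(arc, i, seed = seed)
  })
  tables[[length(tables) + 1L]] <- expand_unbundled(arc, seed = seed)
  all <- rbind_alignment_tables(tables)
  write_sam(all, arc$chroms, sam_out)
  invisible(sam_out)
}
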