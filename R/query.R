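# Targeted queries against an archive: bundle spans (index only), coverage
# (inflates overlapping blocks, never runs read recovery), and alignments
# (runs recovery/pairing on overlapping bundles only). Each bundle expands
# from its own derived RNG stream, so results are independent of which other
# regions were queried.

#' List bundle spans
#'
#' A single uncompressed index lookup; no block is inflated. The spans
#' delimit regions of non-zero coverage, roughly corresponding to genes.
#'
#' @param archive handle from [open_archive()].
#' @return data.frame `chrom`, `start`, `end` in genomic order.
#' @export
query_bundles <- function(archive) {
  archive$bundles[, c("chrom", "start", "end")]
}

.check_region <- function(archive, chrom, start, end) {
  if (!chrom %in% archive$chroms$name) {
    stop("unknown chromosome: ", chrom)
  }
  if (!(start < end)) stop("query region must satisfy start < end")
}

#' Extract the coverage vector over a genomic region
#'
#' Sums the relevant portions of the coverage vectors of all buckets
#' (including bundle-spanning buckets) overlapping the region. Positions
#' inside a bucket's skipped introns contribute zero from that bucket.
#'
#' @param archive handle from [open_archive()].
#' @param chrom,start,end half-open 0-based region.
#' @return integer vector of per-base depths, length `end - start`.
#' @export
query_coverage <- function(archive, chrom, start, end) {
  .check_region(archive, chrom, start, end)
  out <- integer(end - start)
  bsel <- which(archive$bundles$chrom == chrom &
                archive$bundles$start < end &
                archive$bundles$end > start)
  for (i in bsel) {
    blk <- read_bundle_block(archive, i)
    meta <- archive$bundles[i, ]
    bounds <- c(meta$start, blk$cuts, meta$end)
    partitions <- data.frame(start = bounds[-length(bounds)],
                             end = bounds[-1L])
    for (b in blk$buckets) {
      geom <- bucket_geometry(b$spanned, partitions)
      out <- add_geom_coverage(out, start, end, geom,
                               rle_decode(b$coverage))
    }
  }
  # bundle-spanning buckets, located via the chunk index's bundle ranges
  csel <- chunks_for_bundles(archive, chrom, start, end)
  for (ci in csel) {
    for (u in read_unbundled_chunk(archive, ci)) {
      lgeom <- segment_geometry(u$left$iv_start, u$left$iv_end)
      rgeom <- segment_geometry(u$right$iv_start, u$right$iv_end)
      llen <- sum(lgeom$cend - lgeom$cstart)
      cov <- rle_decode(u$coverage)
      if (archive$chroms$name[u$chrom_left] == chrom) {
        out <- add_geom_coverage(out, start, end, lgeom,
                                 cov[seq_len(llen)])
      }
      if (archive$chroms$name[u$chrom_right] == chrom) {
        out <- add_geom_coverage(out, start, end, rgeom,
                                 cov[(llen + 1L):length(cov)])
      }
    }
  }
  out
}

# chunks whose bundle-index range intersects any bundle overlapping the
# region (empty bundles included: unbundled ends may be their only content)
chunks_for_bundles <- function(archive, chrom, start, end) {
  if (nrow(archive$chunks) == 0L) return(integer(0))
  bsel <- which(archive$bundles$chrom == chrom &
                archive$bundles$start < end &
                archive$bundles$end > start)
  if (length(bsel) == 0L) return(integer(0))
  which(archive$chunks$min_bundle <= max(bsel) &
        archive$chunks$max_bundle >= min(bsel))
}

add_geom_coverage <- function(out, qstart, qend, geom, depths) {
  for (k in seq_len(nrow(geom))) {
    gs <- max(geom$gstart[k], qstart)
    ge <- min(geom$gend[k], qend)
    if (gs >= ge) next
    coff <- geom$cstart[k] + (gs - geom$gstart[k])
    idx <- (gs - qstart + 1L):(ge - qstart)
    out[idx] <- out[idx] + depths[(coff + 1L):(coff + (ge - gs))]
  }
  out
}

#' Extract alignments overlapping a genomic region
#'
#' Expands every bundle (and unbundled chunk) overlapping the region with
#' the greedy recovery and pairing algorithms, then filters to alignments
#' with at least one block intersecting the region. Deterministic given
#' `seed`, independently of other queries.
#'
#' @inheritParams query_coverage
#' @param seed archive-level seed.
#' @return alignment table.
#' @export
query_alignments <- function(archive, chrom, start, end, seed = 1L) {
  .check_region(archive, chrom, start, end)
  bsel <- which(archive$bundles$chrom == chrom &
                archive$bundles$start < end &
                archive$bundles$end > start)
  tables <- lapply(bsel, function(i) expand_bundle(archive, i, seed = seed))
  csel <- chunks_for_bundles(archive, chrom, start, end)
  if (length(csel)) {
    tables[[length(tables) + 1L]] <-
      expand_unbundled(archive, seed = seed, chunk_sel = csel)
  }
  all <- rbind_alignment_tables(tables)
  if (nrow(all) == 0L) return(all)
  hit <- vapply(seq_len(nrow(all)), function(k) {
    b <- all$blocks[[k]]
    all$chrom[k] == chrom && any(b[, 1L] < end & b[, 2L] > start)
  }, logical(1))
  out <- all[hit, ]
  rownames(out) <- NULL
  out
}
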