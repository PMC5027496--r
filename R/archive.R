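# Archive layout (all integers LEB128 varints, all blocks zlib-wrapped
# DEFLATE):
#
#   magic "CVP1", version byte
#   chromosome table: n, then per chromosome name-length, name bytes, length
#   bundle index: n_bundles, then per bundle chrom-index (1-based),
#     span start, span length, compressed block length (offsets are the
#     running sums, strictly increasing by construction)
#   unbundled chunk index: n_chunks, then per chunk min bundle index,
#     max bundle index, compressed chunk length (offsets continue after the
#     bundle blocks)
#   data section: bundle blocks in index order, then unbundled chunks
#
# Each bundle block inflates to a flat varint stream:
#   n_cuts, cut deltas from span start; n_buckets; per bucket:
#   n_spanned, spanned ordinal deltas, nh, strand code, n_runs,
#   (depth, run length)*, n_length_entries, (value, count)*, paired_count,
#   n_tlen_entries, (value, count)*
#
# Each unbundled chunk inflates to a flat varint stream of bundle-spanning
# buckets; see encode_unbundled_bucket() for the field order.

ARCHIVE_MAGIC <- charToRaw("CVP1")
ARCHIVE_VERSION <- 1L
UNBUNDLED_CHUNK_SIZE <- 64L

encode_tally <- function(tally) {
  c(nrow(tally), as.numeric(rbind(tally$value, tally$count)))
}

encode_bucket <- function(b) {
  sp <- b$spanned
  c(length(sp), sp[1L], diff(sp),
    b$nh, strand_code(b$strand),
    length(b$coverage$values),
    as.numeric(rbind(b$coverage$values, b$coverage$lengths)),
    encode_tally(b$length_tally),
    b$paired_count,
    encode_tally(b$tlen_tally))
}

encode_bundle_payload <- function(span_start, cuts, buckets) {
  parts <- list(c(length(cuts), diff(c(span_start, cuts)), length(buckets)))
  for (b in buckets) parts[[length(parts) + 1L]] <- encode_bucket(b)
  varint_encode(unlist(parts, use.names = FALSE))
}

encode_side <- function(side) {
  k <- length(side$iv_start)
  gaps <- if (k > 1L) side$iv_start[-1L] - side$iv_end[-k] else numeric(0)
  lens <- side$iv_end - side$iv_start
  c(k, side$iv_start[1L], as.numeric(rbind(lens, c(gaps, 0)))[seq_len(2L * k - 1L)],
    side$nh, strand_code(side$strand))
}

encode_unbundled_bucket <- function(u) {
  c(u$chrom_left, u$chrom_right, u$bundle_left, u$bundle_right,
    encode_side(u$left), encode_side(u$right),
    length(u$coverage$values),
    as.numeric(rbind(u$coverage$values, u$coverage$lengths)),
    encode_tally(u$length_tally),
    u$n_pairs,
    encode_tally(u$tlen_tally))
}

#' Serialize a compressed dataset to an archive file
#'
#' @param build internal build object: `chroms`, `bundles`, `payloads`
#'   (per-bundle `cuts` + `buckets`), `unbundled` (list of bundle-spanning
#'   buckets).
#' @param path output file.
#' @param chunk_size bundle-spanning buckets per unbundled chunk.
#' @return `path`, invisibly.
#' @keywords internal
serialize_archive <- function(build, path,
                              chunk_size = UNBUNDLED_CHUNK_SIZE) {
  nb <- nrow(build$bundles)
  blocks <- vector("list", nb)
  for (i in seq_len(nb)) {
    blocks[[i]] <- memCompress(
      encode_bundle_payload(build$bundles$start[i],
                            build$payloads[[i]]$cuts,
                            build$payloads[[i]]$buckets),
      type = "gzip"
    )
  }
  chunks <- list()
  chunk_meta <- NULL
  if (length(build$unbundled)) {
    grp <- split(build$unbundled,
                 (seq_along(build$unbundled) - 1L) %/% chunk_size)
    for (g in grp) {
      stream <- unlist(lapply(g, encode_unbundled_bucket), use.names = FALSE)
      chunks[[length(chunks) + 1L]] <- memCompress(
        varint_encode(c(length(g), stream)), type = "gzip"
      )
      bidx <- unlist(lapply(g, function(u) c(u$bundle_left, u$bundle_right)))
      chunk_meta <- rbind(chunk_meta, c(min(bidx), max(bidx)))
    }
  }

  hdr <- list(ARCHIVE_MAGIC, as.raw(ARCHIVE_VERSION))
  ct <- list(varint_encode(nrow(build$chroms)))
  for (i in seq_len(nrow(build$chroms))) {
    nm <- charToRaw(build$chroms$name[i])
    ct[[length(ct) + 1L]] <- c(varint_encode(length(nm)), nm,
                               varint_encode(build$chroms$length[i]))
  }
  bidxv <- c(nb, unlist(lapply(seq_len(nb), function(i) {
    c(match(build$bundles$chrom[i], build$chroms$name),
      build$bundles$start[i],
      build$bundles$end[i] - build$bundles$start[i],
      length(blocks[[i]]))
  }), use.names = FALSE))
  cidxv <- c(length(chunks), unlist(lapply(seq_along(chunks), function(i) {
    c(chunk_meta[i, 1L], chunk_meta[i, 2L], length(chunks[[i]]))
  }), use.names = FALSE))

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(unlist(c(hdr, ct,
                    list(varint_encode(bidxv), varint_encode(cidxv)),
                    blocks, chunks), use.names = FALSE), con)
  invisible(path)
}

#' Open an archive and read its header and indexes
#'
#' Reads only the header, chromosome table and indexes; no block is inflated.
#'
#' @param path archive file.
#' @return archive handle: `chroms`, `bundles` (with per-bundle byte `offset`
#'   and `block_len`), `chunks`, and the raw data section.
#' @export
open_archive <- function(path) {
  buf <- readBin(path, "raw", n = file.size(path))
  cur <- raw_cursor(buf)
  magic <- cursor_bytes(cur, 4L)
  if (!identical(magic, ARCHIVE_MAGIC)) {
    stop("not an archive: bad magic in header")
  }
  version <- as.integer(cursor_bytes(cur, 1L))
  if (version != ARCHIVE_VERSION) {
    stop("unsupported archive version in header: ", version)
  }
  nchrom <- cursor_varint(cur)
  cname <- character(nchrom)
  clen <- integer(nchrom)
  for (i in seq_len(nchrom)) {
    nl <- cursor_varint(cur)
    cname[i] <- rawToChar(cursor_bytes(cur, nl))
    clen[i] <- cursor_varint(cur)
  }
  nb <- cursor_varint(cur)
  bidx <- if (nb > 0) matrix(cursor_varint(cur, 4L * nb), ncol = 4L,
                             byrow = TRUE) else matrix(numeric(0), ncol = 4L)
  if (nb > 0 && (any(bidx[, 1L] < 1) || any(bidx[, 1L] > nchrom))) {
    stop("corrupt bundle index: chromosome id out of range")
  }
  nc <- cursor_varint(cur)
  cidx <- if (nc > 0) matrix(cursor_varint(cur, 3L * nc), ncol = 3L,
                             byrow = TRUE) else matrix(numeric(0), ncol = 3L)
  data_start <- cur$pos
  offsets <- cumsum(c(0, bidx[, 4L]))
  chunk_offsets <- offsets[length(offsets)] + cumsum(c(0, cidx[, 3L]))
  total <- chunk_offsets[length(chunk_offsets)]
  if (data_start - 1L + total > length(buf)) {
    stop("archive truncated: data section shorter than index total")
  }
  bundles <- data.frame(
    chrom = cname[bidx[, 1L]],
    start = as.integer(bidx[, 2L]),
    end = as.integer(bidx[, 2L] + bidx[, 3L]),
    offset = offsets[seq_len(nb)],
    block_len = bidx[, 4L],
    stringsAsFactors = FALSE
  )
  chunks <- data.frame(
    min_bundle = as.integer(cidx[, 1L]),
    max_bundle = as.integer(cidx[, 2L]),
    offset = chunk_offsets[seq_len(nc)],
    chunk_len = cidx[, 3L]
  )
  structure(list(
    path = path,
    chroms = data.frame(name = cname, length = clen,
                        stringsAsFactors = FALSE),
    bundles = bundles,
    chunks = chunks,
    data = buf[data_start:length(buf)]
  ), class = "cvp_archive")
}

#' @export
print.cvp_archive <- function(x, ...) {
  cat("coverpress archive:", nrow(x$bundles), "bundles on",
      nrow(x$chroms), "chromosomes;", nrow(x$chunks),
      "unbundled chunks;", length(x$data), "data bytes\n")
  invisible(x)
}

# numeric-vector cursor for decoded varint streams
num_cursor <- function(v) {
  env <- new.env(parent = emptyenv())
  env$v <- v
  env$pos <- 1L
  env
}
num_take <- function(cur, n = 1L) {
  if (n == 0L) return(numeric(0))
  if (cur$pos + n - 1L > length(cur$v)) {
    stop("corrupt block: varint stream ends early")
  }
  out <- cur$v[cur$pos:(cur$pos + n - 1L)]
  cur$pos <- cur$pos + as.integer(n)
  out
}

decode_tally <- function(cur) {
  k <- num_take(cur)
  if (k == 0) return(tally_new())
  m <- matrix(num_take(cur, 2L * k), ncol = 2L, byrow = TRUE)
  data.frame(value = as.integer(m[, 1L]), count = as.integer(m[, 2L]))
}

decode_bucket <- function(cur) {
  ns <- num_take(cur)
  spanned <- as.integer(cumsum(num_take(cur, ns)))
  nh <- as.integer(num_take(cur))
  strand <- strand_decode(num_take(cur))
  nr <- num_take(cur)
  runs <- if (nr > 0) matrix(num_take(cur, 2L * nr), ncol = 2L, byrow = TRUE)
          else matrix(numeric(0), ncol = 2L)
  lt <- decode_tally(cur)
  pc <- as.integer(num_take(cur))
  tt <- decode_tally(cur)
  list(
    spanned = spanned, nh = nh, strand = strand,
    coverage = structure(list(values = as.integer(runs[, 1L]),
                              lengths = as.integer(runs[, 2L])),
                         class = "coverage_rle"),
    length_tally = lt, paired_count = pc, tlen_tally = tt
  )
}

#' Inflate and decode one bundle block
#'
#' @param archive handle from [open_archive()].
#' @param i bundle index.
#' @return list `cuts` (absolute cut positions) and `buckets`.
#' @export
read_bundle_block <- function(archive, i) {
  meta <- archive$bundles[i, ]
  raw <- archive$data[(meta$offset + 1):(meta$offset + meta$block_len)]
  stream <- decode_varint_stream(memDecompress(raw, type = "gzip"))
  cur <- num_cursor(stream)
  ncuts <- num_take(cur)
  cuts <- as.integer(meta$start + cumsum(num_take(cur, ncuts)))
  nb <- num_take(cur)
  buckets <- vector("list", nb)
  for (k in seq_len(nb)) buckets[[k]] <- decode_bucket(cur)
  list(cuts = cuts, buckets = buckets)
}

decode_side <- function(cur) {
  k <- num_take(cur)
  first <- num_take(cur)
  rest <- num_take(cur, 2L * k - 1L)
  lens <- rest[seq(1L, 2L * k - 1L, by = 2L)]
  gaps <- if (k > 1L) rest[seq(2L, 2L * k - 2L, by = 2L)] else numeric(0)
  starts <- first + c(0, cumsum(lens[-k] + gaps))
  nh <- as.integer(num_take(cur))
  strand <- strand_decode(num_take(cur))
  list(iv_start = as.integer(starts),
       iv_end = as.integer(starts + lens),
       nh = nh, strand = strand)
}

#' Inflate and decode one unbundled chunk
#'
#' @param archive handle from [open_archive()].
#' @param i chunk index.
#' @return list of bundle-spanning buckets.
#' @export
read_unbundled_chunk <- function(archive, i) {
  meta <- archive$chunks[i, ]
  raw <- archive$data[(meta$offset + 1):(meta$offset + meta$chunk_len)]
  stream <- decode_varint_stream(memDecompress(raw, type = "gzip"))
  cur <- num_cursor(stream)
  n <- num_take(cur)
  out <- vector("list", n)
  for (k in seq_len(n)) {
    cl <- num_take(cur)
    cr <- num_take(cur)
    bl <- num_take(cur)
    br <- num_take(cur)
    if (bl > nrow(archive$bundles) || br > nrow(archive$bundles)) {
      stop("corrupt unbundled chunk: dangling bundle index")
    }
    left <- decode_side(cur)
    right <- decode_side(cur)
    nr <- num_take(cur)
    runs <- if (nr > 0) matrix(num_take(cur, 2L * nr), ncol = 2L,
                               byrow = TRUE)
            else matrix(numeric(0), ncol = 2L)
    lt <- decode_tally(cur)
    np <- as.integer(num_take(cur))
    tt <- decode_tally(cur)
    out[[k]] <- list(
      chrom_left = as.integer(cl), chrom_right = as.integer(cr),
      bundle_left = as.integer(bl), bundle_right = as.integer(br),
      left = left, right = right,
      coverage = structure(list(values = as.integer(runs[, 1L]),
                                lengths = as.integer(runs[, 2L])),
                           class = "coverage_rle"),
      length_tally = lt, n_pairs = np, tlen_tally = tt
    )
  }
  out
}
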