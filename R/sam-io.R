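# SAM round-tripping. Internally every alignment lives in a plain data.frame
# ("alignment table") with 0-based half-open coordinates; conversion to/from
# 1-based SAM happens only here.
#
# Columns of an alignment table:
#   chrom      reference name
#   start      0-based leftmost aligned position
#   end        0-based position one past the rightmost aligned base
#   blocks     list column of integer matrices (start, end): aligned intervals
#              split at N operations
#   length     total aligned read length (sum of block lengths + insertions)
#   strand     "+", "-" or "*" (from XS:A; "*" = unknown)
#   nh         reported alignment count (NH:i, default 1)
#   paired     TRUE if this end belongs to a mapped pair
#   mate_chrom, mate_start  mate location (NA when unpaired)
#   tlen       signed genomic outer distance as in SAM TLEN (0 when unpaired)
#   pair_id    integer linking the two rows of one pair (NA when unpaired)

#' Construct an alignment table
#'
#' @param chrom,start,blocks,length,strand,nh,paired,mate_chrom,mate_start,tlen,pair_id
#'   column vectors; see the format description in the package source.
#' @return data.frame of class `alignment_table`.
#' @keywords internal
alignment_table <- function(chrom = character(0), start = integer(0),
                            blocks = list(), length = integer(0),
                            strand = character(0), nh = integer(0),
                            paired = logical(0), mate_chrom = character(0),
                            mate_start = integer(0), tlen = integer(0),
                            pair_id = integer(0)) {
  n <- base::length(chrom)
  end <- vapply(blocks, function(b) as.integer(b[nrow(b), 2L]), integer(1))
  df <- data.frame(
    chrom = as.character(chrom),
    start = as.integer(start),
    end = if (n) end else integer(0),
    length = as.integer(length),
    strand = as.character(strand),
    nh = as.integer(nh),
    paired = as.logical(paired),
    mate_chrom = as.character(mate_chrom),
    mate_start = as.integer(mate_start),
    tlen = as.integer(tlen),
    pair_id = as.integer(pair_id),
    stringsAsFactors = FALSE
  )
  df$blocks <- blocks
  class(df) <- c("alignment_table", "data.frame")
  df
}

empty_alignment_table <- function() {
  alignment_table(
    chrom = character(0), start = integer(0), blocks = list(),
    length = integer(0), strand = character(0), nh = integer(0),
    paired = logical(0), mate_chrom = character(0),
    mate_start = integer(0), tlen = integer(0), pair_id = integer(0)
  )
}

.sam_tag <- function(tails, pattern) {
  m <- regexpr(pattern, tails, perl = TRUE)
  out <- rep(NA_character_, length(tails))
  hit <- m != -1L
  out[hit] <- regmatches(tails, m)[seq_len(sum(hit))]
  out
}

#' Read aligned records from a SAM (or BAM) file
#'
#' Unaligned records are skipped. An end whose mate is unmapped (or whose
#' mate record is absent) is demoted to an unpaired read; the pairing of
#' orphans is not preserved. Missing `NH:i` defaults to 1 and missing `XS:A`
#' to unknown strand. Input must be coordinate-sorted.
#'
#' @param path SAM text file, or a BAM file (requires Rsamtools).
#' @return list with `chroms` (data.frame `name`, `length` from the \code{@SQ}
#'   header lines) and `alignments` (an alignment table).
#' @export
read_sam <- function(path) {
  if (grepl("\\.bam$", path, ignore.case = TRUE)) {
    return(read_bam_adapter(path))
  }
  lines <- readLines(path)
  is_hdr <- startsWith(lines, "@")
  hdr <- lines[is_hdr]
  body <- lines[!is_hdr]
  body <- body[nzchar(body)]
  sq <- hdr[startsWith(hdr, "@SQ")]
  chroms <- data.frame(
    name = sub(".*\tSN:([^\t]+).*", "\\1", sq),
    length = as.integer(sub(".*\tLN:([0-9]+).*", "\\1", sq)),
    stringsAsFactors = FALSE
  )
  if (length(body) == 0L) {
    return(list(chroms = chroms, alignments = empty_alignment_table()))
  }
  f <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(f)
  if (any(nf < 11L)) {
    stop("SAM record ", which(nf < 11L)[1], " has fewer than 11 fields")
  }
  qname <- vapply(f, `[[`, "", 1L)
  flag <- as.integer(vapply(f, `[[`, "", 2L))
  rname <- vapply(f, `[[`, "", 3L)
  pos <- as.integer(vapply(f, `[[`, "", 4L))
  cigar <- vapply(f, `[[`, "", 6L)
  rnext <- vapply(f, `[[`, "", 7L)
  pnext <- as.integer(vapply(f, `[[`, "", 8L))
  tlen <- as.integer(vapply(f, `[[`, "", 9L))
  tails <- vapply(f, function(x) {
    if (length(x) > 11L) paste(x[-(1:11)], collapse = "\t") else ""
  }, "")

  aligned <- bitwAnd(flag, 4L) == 0L & rname != "*" & cigar != "*"
  keep <- which(aligned)
  if (length(keep) == 0L) {
    return(list(chroms = chroms, alignments = empty_alignment_table()))
  }
  # sortedness: positions non-decreasing within each chromosome run, and no
  # chromosome may reappear after another intervened
  rk <- rname[keep]
  pk <- pos[keep]
  runs <- rle(rk)
  if (anyDuplicated(runs$values)) {
    first_bad <- cumsum(runs$lengths)[
      which(duplicated(runs$values))[1] - 1L] + 1L
    stop("input not coordinate-sorted: record ", keep[first_bad],
         " returns to a previously seen chromosome")
  }
  same <- c(FALSE, rk[-length(rk)] == rk[-1L])
  bad <- which(same & c(FALSE, diff(pk) < 0L))
  if (length(bad)) {
    stop("input not coordinate-sorted: record ", keep[bad[1]],
         " starts before its predecessor")
  }

  nh <- .sam_tag(tails[keep], "NH:i:[0-9]+")
  nh <- ifelse(is.na(nh), 1L, as.integer(sub("NH:i:", "", nh, fixed = TRUE)))
  xs <- .sam_tag(tails[keep], "XS:A:[+-]")
  strand <- ifelse(is.na(xs), "*", sub("XS:A:", "", xs, fixed = TRUE))

  fk <- flag[keep]
  has_pair_flag <- bitwAnd(fk, 1L) == 1L
  mate_unmapped <- bitwAnd(fk, 8L) == 8L
  paired <- has_pair_flag & !mate_unmapped
  # a "paired" end whose mate record never shows up is also an orphan
  qk <- qname[keep]
  if (any(paired)) {
    cnt <- table(qk[paired])
    solo <- names(cnt)[cnt != 2L]
    paired[paired & qk %in% solo] <- FALSE
  }
  pair_id <- rep(NA_integer_, length(keep))
  if (any(paired)) {
    pair_id[paired] <- match(qk[paired], unique(qk[paired]))
  }

  parsed <- parse_cigar_many(cigar[keep], pos[keep] - 1L)
  mate_chrom <- ifelse(paired,
                       ifelse(rnext[keep] == "=", rname[keep], rnext[keep]),
                       NA_character_)
  out <- alignment_table(
    chrom = rname[keep],
    start = pos[keep] - 1L,
    blocks = parsed$blocks,
    length = parsed$length,
    strand = strand,
    nh = nh,
    paired = paired,
    mate_chrom = mate_chrom,
    mate_start = ifelse(paired, pnext[keep] - 1L, NA_integer_),
    tlen = ifelse(paired, tlen[keep], 0L),
    pair_id = pair_id
  )
  list(chroms = chroms, alignments = out)
}

# BAM adapter via Rsamtools, exposing the same alignment table.
read_bam_adapter <- function(path) {
  if (!requireNamespace("Rsamtools", quietly = TRUE)) {
    stop("reading BAM requires the Rsamtools package")
  }
  tf <- tempfile(fileext = ".sam")
  on.exit(unlink(tf))
  # round through SAM text so tag/orphan/sortedness handling is identical
  Rsamtools::asSam(path, sub("\\.sam$", "", tf), overwrite = TRUE)
  read_sam(tf)
}

#' Write an alignment table as coordinate-sorted SAM
#'
#' Read names are synthetic (`r<counter>`; the two ends of a pair share one),
#' sequence and quality are `*`. Pairs carry symmetric TLEN (leftmost end
#' positive) and mutual mate fields.
#'
#' @param alignments alignment table.
#' @param chroms data.frame with `name` and `length` for the \code{@SQ} lines.
#' @param path output file.
#' @export
write_sam <- function(alignments, chroms, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "@HD\tVN:1.6\tSO:coordinate",
    sprintf("@SQ\tSN:%s\tLN:%d", chroms$name, chroms$length)
  ), con)
  a <- alignments
  if (nrow(a) == 0L) return(invisible(path))
  if (any(a$paired & is.na(a$pair_id))) {
    stop("paired alignment without pair_id cannot be serialized")
  }
  if (any(a$paired)) {
    pc <- table(a$pair_id[a$paired])
    if (any(pc != 2L)) stop("pair with a missing or duplicated end")
    mism <- a$paired & (is.na(a$mate_chrom) | is.na(a$mate_start))
    if (any(mism)) stop("paired alignment with incomplete mate fields")
  }
  ord <- order(match(a$chrom, chroms$name), a$start)
  a <- a[ord, ]
  # names: one per unpaired read / per pair
  name <- character(nrow(a))
  unp <- !a$paired
  ids <- integer(nrow(a))
  ids[unp] <- seq_len(sum(unp))
  if (any(a$paired)) {
    ids[a$paired] <- sum(unp) + match(a$pair_id[a$paired],
                                      unique(a$pair_id[a$paired]))
  }
  name <- paste0("r", ids)
  flag <- integer(nrow(a))
  if (any(a$paired)) {
    first_of_pair <- a$paired & !duplicated(a$pair_id) & !is.na(a$pair_id)
    flag[a$paired] <- 1L + 2L + ifelse(first_of_pair[a$paired], 64L, 128L)
  }
  cig <- vapply(a$blocks, blocks_to_cigar, "")
  rnext <- rep("*", nrow(a))
  pnext <- rep(0L, nrow(a))
  tl <- a$tlen
  if (any(a$paired)) {
    samec <- a$mate_chrom == a$chrom
    rnext[a$paired] <- ifelse(samec[a$paired], "=", a$mate_chrom[a$paired])
    pnext[a$paired] <- a$mate_start[a$paired] + 1L
  }
  tags <- sprintf("NH:i:%d", a$nh)
  has_xs <- a$strand != "*"
  tags[has_xs] <- paste0(tags[has_xs], "\tXS:A:", a$strand[has_xs])
  writeLines(sprintf("%s\t%d\t%s\t%d\t50\t%s\t%s\t%d\t%d\t*\t*\t%s",
                     name, flag, a$chrom, a$start + 1L, cig,
                     rnext, pnext, tl, tags), con)
  invisible(path)
}
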