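# CIGAR handling. Alignments are reduced to "blocks": maximal aligned genomic
# intervals separated only by N (intron) operations. D is folded into the
# enclosing block and I adds to read length, so a decompressed CIGAR contains
# only M and N — the format keeps coverage-relevant shape only.

.cigar_re <- "([0-9]+)([MIDNSHP=X])"

#' Parse a SAM CIGAR string into aligned blocks
#'
#' Splits the alignment at `N` operations only. `M`, `=`, `X` consume
#' reference within the current block; `D` is folded into the enclosing
#' block; `I`, `S`, `H`, `P` are flattened away. The reported length is the
#' genomic footprint (sum of block lengths), the only notion of read length
#' the coverage-domain format can represent.
#'
#' @param cigar a single CIGAR string.
#' @param start 0-based leftmost aligned position.
#' @return list with `blocks` (integer matrix, columns `start`, `end`,
#'   half-open) and `length` (total aligned read length).
#' @examples
#' parse_cigar("50M200N50M", 1000L)
#' @export
parse_cigar <- function(cigar, start = 0L) {
  ops <- cigar_ops(cigar)
  blocks_from_ops(ops$len, ops$op, as.numeric(start))
}

cigar_ops <- function(cigar) {
  if (length(cigar) != 1L || is.na(cigar) || !nzchar(cigar) || cigar == "*") {
    stop("malformed CIGAR: ", deparse(cigar))
  }
  m <- gregexpr(.cigar_re, cigar, perl = TRUE)[[1]]
  toks <- regmatches(cigar, list(m))[[1]]
  if (sum(nchar(toks)) != nchar(cigar)) {
    # locate the first character not consumed by a valid token
    covered <- rep(FALSE, nchar(cigar))
    if (m[1] != -1) {
      for (i in seq_along(m)) {
        covered[m[i]:(m[i] + attr(m, "match.length")[i] - 1L)] <- TRUE
      }
    }
    bad <- which(!covered)[1]
    stop(sprintf(
      "malformed CIGAR %s: unexpected token at position %d ('%s')",
      cigar, bad, substr(cigar, bad, bad)
    ))
  }
  list(
    len = as.integer(sub("[A-Z=]$", "", toks)),
    op = substring(toks, nchar(toks))
  )
}

blocks_from_ops <- function(lens, ops, start) {
  bs <- numeric(0)
  be <- numeric(0)
  cur_s <- start
  cur_e <- start
  open <- FALSE
  for (i in seq_along(ops)) {
    op <- ops[i]
    l <- lens[i]
    if (op == "M" || op == "=" || op == "X") {
      if (!open) {
        cur_s <- cur_e
        open <- TRUE
      }
      cur_e <- cur_e + l
    } else if (op == "D") {
      if (open) cur_e <- cur_e + l else cur_s <- cur_e <- cur_e + l
    } else if (op == "N") {
      if (open) {
        bs <- c(bs, cur_s)
        be <- c(be, cur_e)
        open <- FALSE
      }
      cur_e <- cur_e + l
    }
    # I/S/H/P: no effect on blocks; the stored alignment length is the
    # genomic footprint (sum of block lengths), so insertions are flattened
    # away entirely and per-bucket coverage/length-tally conservation holds
    # exactly
  }
  if (open) {
    bs <- c(bs, cur_s)
    be <- c(be, cur_e)
  }
  if (length(bs) == 0L) {
    stop("CIGAR describes no aligned bases")
  }
  blocks <- cbind(start = as.integer(bs), end = as.integer(be))
  list(blocks = blocks, length = sum(blocks[, 2L] - blocks[, 1L]))
}

# Vectorized parse: unique CIGARs are parsed once at start 0, then offset;
# the ubiquitous single-match case bypasses the tokenizer entirely.
parse_cigar_many <- function(cigars, starts) {
  n <- length(cigars)
  blocks <- vector("list", n)
  lens <- integer(n)
  simple <- grepl("^[0-9]+M$", cigars)
  if (any(simple)) {
    sl <- as.integer(sub("M", "", cigars[simple], fixed = TRUE))
    ss <- as.integer(starts[simple])
    blocks[simple] <- lapply(seq_along(sl), function(k) {
      cbind(start = ss[k], end = ss[k] + sl[k])
    })
    lens[simple] <- sl
  }
  rest <- which(!simple)
  if (length(rest)) {
    uc <- unique(cigars[rest])
    parsed <- lapply(uc, function(cg) parse_cigar(cg, 0L))
    idx <- match(cigars[rest], uc)
    for (k in seq_along(rest)) {
      i <- rest[k]
      p <- parsed[[idx[k]]]
      b <- p$blocks
      b[, 1L] <- b[, 1L] + starts[i]
      b[, 2L] <- b[, 2L] + starts[i]
      blocks[[i]] <- b
      lens[i] <- p$length
    }
  }
  list(blocks = blocks, length = lens)
}

#' Emit an M/N-only CIGAR from aligned blocks
#'
#' Inverse of [parse_cigar()] modulo indel flattening.
#' @param blocks integer matrix of half-open genomic intervals.
#' @return CIGAR string.
#' @export
blocks_to_cigar <- function(blocks) {
  n <- nrow(blocks)
  if (n == 1L) return(paste0(blocks[1L, 2L] - blocks[1L, 1L], "M"))
  parts <- character(2L * n - 1L)
  parts[seq(1L, 2L * n - 1L, by = 2L)] <-
    paste0(blocks[, 2L] - blocks[, 1L], "M")
  if (n > 1L) {
    gaps <- blocks[-1L, 1L] - blocks[-n, 2L]
    parts[seq(2L, 2L * n - 2L, by = 2L)] <- paste0(gaps, "N")
  }
  paste(parts, collapse = "")
}

# Junctions (intron gaps) of one block matrix: matrix with donor/acceptor.
blocks_junctions <- function(blocks) {
  n <- nrow(blocks)
  if (n < 2L) {
    return(cbind(donor = integer(0), acceptor = integer(0)))
  }
  cbind(donor = blocks[-n, 2L], acceptor = blocks[-1L, 1L])
}
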