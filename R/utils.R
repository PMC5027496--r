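# Low-level helpers: LEB128 varints, flat varint streams, seeded RNG scopes.
# Integers are carried as doubles so byte offsets past 2^31 remain exact
# (doubles are exact to 2^53).

#' Encode non-negative integers as LEB128 varints
#'
#' @param x numeric vector of non-negative integers.
#' @return raw vector, concatenated little-endian base-128 encoding.
#' @keywords internal
varint_encode <- function(x) {
  x <- as.numeric(x)
  if (length(x) == 0L) return(raw(0))
  if (anyNA(x) || any(x < 0)) stop("varint values must be non-negative")
  if (all(x < 128)) return(as.raw(x))
  out <- vector("list", length(x))
  for (i in seq_along(x)) {
    v <- x[[i]]
    if (v < 128) {
      out[[i]] <- as.raw(v)
      next
    }
    b <- integer(0)
    repeat {
      lo <- v %% 128
      v <- (v - lo) / 128
      if (v > 0) b <- c(b, lo + 128) else {
        b <- c(b, lo)
        break
      }
    }
    out[[i]] <- as.raw(b)
  }
  unlist(out, use.names = FALSE)
}

#' Decode a buffer consisting solely of varints
#'
#' Vectorized over the whole buffer: used for block payloads, which are flat
#' varint streams by construction.
#' @keywords internal
decode_varint_stream <- function(buf) {
  if (length(buf) == 0L) return(numeric(0))
  b <- as.integer(buf)
  term <- b < 128L
  if (!term[length(b)]) stop("truncated varint stream")
  idx_end <- which(term)
  lens <- diff(c(0L, idx_end))
  payload <- ifelse(term, b, b - 128L)
  grp <- rep.int(seq_along(lens), lens)
  posin <- sequence(lens) - 1
  as.numeric(rowsum(payload * 128^posin, grp))
}

# Scalar cursor over a raw vector, for the header/index sections where raw
# bytes (names, magic) interleave with varints.
raw_cursor <- function(buf) {
  env <- new.env(parent = emptyenv())
  env$buf <- buf
  env$pos <- 1L
  env
}

cursor_bytes <- function(cur, n) {
  if (n == 0) return(raw(0))
  if (cur$pos + n - 1L > length(cur$buf)) stop("archive truncated")
  out <- cur$buf[cur$pos:(cur$pos + n - 1L)]
  cur$pos <- cur$pos + as.integer(n)
  out
}

cursor_varint <- function(cur, n = 1L) {
  out <- numeric(n)
  buf <- cur$buf
  p <- cur$pos
  for (i in seq_len(n)) {
    v <- 0
    mult <- 1
    repeat {
      if (p > length(buf)) stop("archive truncated in varint")
      byte <- as.integer(buf[p])
      p <- p + 1L
      if (byte >= 128L) {
        v <- v + (byte - 128L) * mult
        mult <- mult * 128
      } else {
        v <- v + byte * mult
        break
      }
    }
    out[i] <- v
  }
  cur$pos <- p
  out
}

#' Evaluate code with a temporary RNG state
#'
#' Sets the seed, runs `expr`, and restores the caller's `.Random.seed`,
#' so library randomness never perturbs user code.
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# Derive a per-bundle RNG seed from the archive-level seed so each bundle's
# expansion is independent of which other bundles were expanded first.
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) %% 2^31 + (index + 1) * 1000003) %% 2147483647)
}

# ---- integer tallies -------------------------------------------------------

#' Build a tally (multiset of integers with counts)
#'
#' @param values integer vector (with repeats) to tally.
#' @return data.frame with columns `value`, `count`, sorted by value.
#' @export
tally_new <- function(values = integer(0)) {
  if (length(values) == 0L) {
    return(data.frame(value = integer(0), count = integer(0)))
  }
  tab <- table(as.integer(values))
  data.frame(
    value = as.integer(names(tab)),
    count = as.integer(tab),
    row.names = NULL
  )
}

#' @rdname tally_new
#' @param tally a tally data.frame.
#' @export
tally_total <- function(tally) sum(tally$count)

# Merge tallies by summing counts.
tally_merge <- function(...) {
  all <- do.call(rbind, list(...))
  if (is.null(all) || nrow(all) == 0L) return(tally_new())
  agg <- rowsum(all$count, all$value)
  data.frame(
    value = as.integer(rownames(agg)),
    count = as.integer(agg),
    row.names = NULL
  )
}
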