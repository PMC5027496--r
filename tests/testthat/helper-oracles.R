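# Independent oracles used across the suite. These deliberately take the
# dumbest correct route (per-base pileups, exhaustive search) so they share
# no code path with the implementation they certify.

# brute-force per-base pileup of an alignment table over [start, end)
pileup_oracle <- function(alignments, chrom, start, end) {
  out <- integer(end - start)
  a <- alignments[alignments$chrom == chrom, ]
  for (k in seq_len(nrow(a))) {
    b <- a$blocks[[k]]
    for (r in seq_len(nrow(b))) {
      s <- max(b[r, 1L], start)
      e <- min(b[r, 2L], end)
      if (s < e) {
        idx <- (s - start + 1L):(e - start)
        out[idx] <- out[idx] + 1L
      }
    }
  }
  out
}

# Exhaustive read-recovery optimum: maximum total placed length such that
# lengths come from the tally and induced coverage never exceeds cov.
# Any read covering the leftmost nonzero position p must start there, so the
# branch set is {place each feasible length at p} + {waste p}. Wasting can
# skip the whole residual run: by an exchange argument (a read whose left
# neighbor has leftover coverage can shift one base left, preserving
# feasibility and total length), some optimal solution never starts a read
# immediately right of a wasted unit, so once p is wasted the entire
# remaining positive run is unusable. Exact branch-and-bound: an optional
# incumbent (any feasible total, e.g. the greedy result) and dominance
# memoization only prune, never change the optimum.
oracle_recover_total <- function(cov, tally, incumbent = 0) {
  lens <- rep(tally$value, tally$count)
  ub0 <- min(sum(lens), sum(cov))
  best <- min(incumbent, ub0)
  if (best >= ub0) return(ub0)
  n <- length(cov)
  seen <- new.env(parent = emptyenv())
  # coverage in any positive run shorter than the smallest remaining length
  # can never be consumed
  usable_cov <- function(cov, lmin) {
    r <- rle(cov > 0)
    ends <- cumsum(r$lengths)
    tot <- 0
    for (k in which(r$values & r$lengths >= lmin)) {
      tot <- tot + sum(cov[(ends[k] - r$lengths[k] + 1L):ends[k]])
    }
    tot
  }
  rec <- function(cov, rem, acc) {
    if (best >= ub0) return(invisible())
    if (length(rem) == 0L ||
        acc + min(sum(rem), usable_cov(cov, min(rem))) <= best) {
      if (acc > best) best <<- acc
      return(invisible())
    }
    p <- which(cov > 0)[1L]
    if (is.na(p) || length(rem) == 0L) {
      if (acc > best) best <<- acc
      return(invisible())
    }
    # dominance pruning: revisit a residual state only with a higher total
    key <- paste(p, paste(rem, collapse = ","),
                 paste(cov[p:n], collapse = ","), sep = "|")
    prev <- seen[[key]]
    if (!is.null(prev) && prev >= acc) return(invisible())
    seen[[key]] <- acc
    for (L in sort(unique(rem), decreasing = TRUE)) {
      if (p + L - 1L <= n && all(cov[p:(p + L - 1L)] > 0)) {
        cov2 <- cov
        cov2[p:(p + L - 1L)] <- cov2[p:(p + L - 1L)] - 1L
        rec(cov2, rem[-match(L, rem)], acc + L)
      }
    }
    cov2 <- cov
    runend <- p
    while (runend < n && cov2[runend + 1L] > 0) runend <- runend + 1L
    cov2[p:runend] <- 0L
    rec(cov2, rem, acc)
  }
  rec(cov, lens, 0)
  best
}

# exhaustive monotone one-to-one exon matching score
oracle_transcript_score <- function(ex1, ex2, k = 10) {
  n1 <- nrow(ex1)
  n2 <- nrow(ex2)
  best <- 0
  rec <- function(i, j, acc) {
    if (i > n1 || j > n2) {
      if (acc > best) best <<- acc
      return(invisible())
    }
    rec(i + 1L, j, acc)
    rec(i, j + 1L, acc)
    rec(i + 1L, j + 1L, acc + exon_score(ex1[i, ], ex2[j, ], k))
  }
  rec(1L, 1L, 0)
  best / max(n1, n2)
}

# build a one-row-per-read alignment table from explicit block matrices
make_aln <- function(chrom, blocks_list, strand = NULL, nh = NULL,
                     paired = NULL, pair_id = NULL, tlen = NULL,
                     mate_start = NULL) {
  n <- length(blocks_list)
  strand <- strand %||% rep("*", n)
  nh <- nh %||% rep(1L, n)
  paired <- paired %||% rep(FALSE, n)
  pair_id <- pair_id %||% rep(NA_integer_, n)
  tlen <- tlen %||% rep(0L, n)
  mate_start <- mate_start %||% rep(NA_integer_, n)
  coverpress:::alignment_table(
    chrom = rep(chrom, n),
    start = vapply(blocks_list, function(b) b[1L, 1L], integer(1)),
    blocks = blocks_list,
    length = vapply(blocks_list, function(b) sum(b[, 2L] - b[, 1L]),
                    integer(1)),
    strand = strand, nh = nh, paired = paired,
    mate_chrom = ifelse(paired, chrom, NA_character_),
    mate_start = mate_start, tlen = tlen, pair_id = pair_id
  )
}

blk <- function(...) {
  v <- c(...)
  matrix(as.integer(v), ncol = 2L, byrow = TRUE,
         dimnames = list(NULL, c("start", "end")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# coverage induced by recovered reads, for safety checks (concat space)
induced_coverage <- function(reads, n) {
  out <- integer(n)
  for (k in seq_len(nrow(reads))) {
    idx <- (reads$start[k] + 1L):(reads$end[k])
    out[idx] <- out[idx] + 1L
  }
  out
}

# random bucket: place reads, return stored vector + tally + truth
random_bucket <- function(n_reads, lengths, span = 400L) {
  ls <- sample(lengths, n_reads, replace = TRUE)
  ss <- vapply(ls, function(l) sample.int(span - l + 1L, 1L) - 1L,
               integer(1))
  reads <- data.frame(start = ss, end = ss + ls)
  cov <- induced_coverage(reads, span)
  list(coverage = rle_encode(cov), tally = tally_new(ls),
       cov = cov, truth = reads)
}
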