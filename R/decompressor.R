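# Read recovery and pairing. Recovery reconstructs a multiset of intervals
# from a coverage vector and a read-length tally; lengths must come from the
# tally, induced coverage may never exceed the stored vector, and total
# placed length is to be maximized. Uniform-length buckets are solved
# exactly in closed form; mixed-length buckets use a left-to-right greedy
# scan with bounded lengthen/shorten repair, favoring coverage fidelity over
# length-distribution fidelity.

#' Recover read intervals from a coverage vector and length tally
#'
#' @param coverage `coverage_rle` object.
#' @param length_tally tally of read lengths (see [tally_new()]).
#' @param k_repair maximum number of bases a read may be artificially
#'   lengthened or shortened to fix a small coverage discrepancy.
#' @return data.frame `start`, `end` (0-based half-open, in the coverage
#'   vector's coordinate space), sorted by start.
#' @export
recover_reads <- function(coverage, length_tally, k_repair = 5L) {
  cov <- rle_decode(coverage)
  n <- length(cov)
  empty <- data.frame(start = integer(0), end = integer(0))
  if (n == 0L || sum(cov) == 0 || nrow(length_tally) == 0L) return(empty)
  if (nrow(length_tally) == 1L) {
    res <- recover_uniform(cov, length_tally$value[1L])
    if (!is.null(res)) return(res)
  }
  # mixed lengths: the scan is run under a few deterministic tie-break
  # strategies and the solution placing the most total length (coverage
  # fidelity first) wins; ties resolve to the first strategy
  best <- NULL
  best_len <- -1
  for (strat in c("frag_longest", "frag_shortest", "longest", "shortest",
                  "rollout")) {
    r <- if (strat == "rollout") {
      recover_rollout(cov, length_tally$value, length_tally$count, k_repair)
    } else {
      recover_greedy(cov, length_tally$value, length_tally$count,
                     k_repair, strat)
    }
    tot <- sum(r$end - r$start)
    if (tot > best_len) {
      best <- r
      best_len <- tot
    }
    if (best_len >= sum(cov)) break
  }
  best
}

# One-step rollout: at each extraction point, score every consistent length
# by completing the scan with the fragment-aware greedy, and commit to the
# best-scoring choice. Deterministic; quadratic in bucket size.
recover_rollout <- function(cov, lens, cnts, k_repair) {
  rem <- cnts
  n <- length(cov)
  rs <- integer(0)
  re_ <- integer(0)
  pos <- 1L
  while (pos <= n) {
    if (cov[pos] == 0) {
      pos <- pos + 1L
      next
    }
    runend <- pos
    while (runend < n && cov[runend + 1L] > 0) runend <- runend + 1L
    runlen <- runend - pos + 1L
    avail <- unique(lens[rem > 0 & lens <= runlen])
    if (length(avail) == 0L) {
      # delegate the repair decision to the base greedy on the rest
      tail_ <- recover_greedy(cov, lens, rem, k_repair, "frag_longest")
      out <- rbind(data.frame(start = rs - 1L, end = re_ - 1L), tail_)
      return(out[order(out$start, out$end), , drop = FALSE])
    }
    avail <- sort(avail, decreasing = TRUE)
    best_L <- avail[1L]
    best_tot <- -1
    for (L in avail) {
      cov2 <- cov
      cov2[pos:(pos + L - 1L)] <- cov2[pos:(pos + L - 1L)] - 1L
      rem2 <- rem
      rem2[match(L, lens)] <- rem2[match(L, lens)] - 1L
      sim <- recover_greedy(cov2, lens, rem2, k_repair, "frag_longest")
      tot <- L + sum(sim$end - sim$start)
      if (tot > best_tot) {
        best_tot <- tot
        best_L <- L
      }
    }
    cov[pos:(pos + best_L - 1L)] <- cov[pos:(pos + best_L - 1L)] - 1L
    rem[match(best_L, lens)] <- rem[match(best_L, lens)] - 1L
    rs <- c(rs, pos)
    re_ <- c(re_, pos + best_L)
  }
  out <- data.frame(start = rs - 1L, end = re_ - 1L)
  out[order(out$start, out$end), , drop = FALSE]
}

# Closed form for a single read length L: with d[i] the coverage increment at
# position i, the start counts satisfy s[i] = d[i] + s[i - L], i.e. cumulative
# sums of d within residue classes mod L. Valid (and then the unique exact
# solution) iff all s >= 0 and no read overruns the vector.
recover_uniform <- function(cov, L) {
  n <- length(cov)
  if (n < L) return(NULL)
  d <- diff(c(0L, cov))
  cls <- (seq_len(n) - 1L) %% L
  s <- stats::ave(d, cls, FUN = cumsum)
  if (any(s < 0)) return(NULL)
  if (L > 1L && any(s[(n - L + 2L):n] > 0)) return(NULL)
  pos <- which(s > 0)
  if (length(pos) == 0L) return(NULL)
  starts <- rep(pos, s[pos]) - 1L
  data.frame(start = as.integer(starts), end = as.integer(starts + L))
}

recover_greedy <- function(cov, lens, cnts, k_repair,
                           strategy = "frag_longest") {
  n <- length(cov)
  rem <- cnts
  rs <- integer(0)
  re_ <- integer(0)
  pos <- 1L
  while (pos <= n) {
    if (cov[pos] == 0) {
      pos <- pos + 1L
      next
    }
    # maximal positive run starting at pos
    runend <- pos
    while (runend < n && cov[runend + 1L] > 0) runend <- runend + 1L
    runlen <- runend - pos + 1L
    avail <- lens[rem > 0 & lens <= runlen]
    if (length(avail)) {
      pick <- choose_length(cov, pos, runend, avail, lens, rem, strategy)
      cov[pos:(pos + pick - 1L)] <- cov[pos:(pos + pick - 1L)] - 1L
      rem[match(pick, lens)] <- rem[match(pick, lens)] - 1L
      rs <- c(rs, pos)
      re_ <- c(re_, pos + pick)
    } else {
      if (all(rem == 0)) {
        # tally exhausted: remaining coverage stays unconsumed
        pos <- runend + 1L
        next
      }
      # every remaining tallied length exceeds the run: bounded repair
      cand <- lens[rem > 0]
      nearest <- cand[which.min(abs(cand - runlen))]
      if (abs(nearest - runlen) <= k_repair) {
        cov[pos:runend] <- cov[pos:runend] - 1L
        rem[match(nearest, lens)] <- rem[match(nearest, lens)] - 1L
        rs <- c(rs, pos)
        re_ <- c(re_, pos + runlen)
      } else {
        pos <- runend + 1L
      }
    }
  }
  out <- data.frame(start = rs - 1L, end = re_ - 1L)
  out[order(out$start, out$end), , drop = FALSE]
}

# Tie-break among consistent lengths. The fragment-aware strategies prefer a
# length whose removal leaves no positive-coverage fragment shorter than the
# smallest remaining tallied length (such fragments could never be consumed
# exactly); plain strategies just take the longest/shortest consistent
# length. If no length passes the fragment check, fall back to the first.
choose_length <- function(cov, pos, runend, avail, lens, rem,
                          strategy = "frag_longest") {
  avail <- sort(avail, decreasing = strategy %in% c("frag_longest",
                                                    "longest"))
  if (strategy %in% c("longest", "shortest")) return(avail[1L])
  for (L in avail) {
    rem2 <- rem
    rem2[match(L, lens)] <- rem2[match(L, lens)] - 1L
    if (all(rem2 == 0)) return(L)
    lmin <- min(lens[rem2 > 0])
    w <- cov[pos:runend]
    w[seq_len(L)] <- w[seq_len(L)] - 1L
    r <- rle(w > 0)
    frag <- r$lengths[r$values]
    if (length(frag) == 0L || all(frag >= lmin)) return(L)
  }
  avail[1L]
}

#' Greedily pair recovered reads against an outer-distance tally
#'
#' First pass examines unpaired reads alternating between the leftmost and
#' rightmost extremes; each seeks the most distant unpaired partner whose
#' genomic outer distance (rightmost end minus leftmost start, introns
#' included) has remaining count in the tally. Reads left over are matched
#' randomly in a second pass, up to `paired_count` ends in total; the rest
#' are returned as singles. Uses the current RNG state for the second pass.
#'
#' @param starts,ends genomic outer coordinates of the recovered reads.
#' @param tlen_tally tally of genomic outer distances.
#' @param paired_count maximum number of ends that may end up in pairs.
#' @return list `pairs` (data.frame `i`, `j`, `dist`; `i` is the leftmost
#'   end) and `singles` (integer indices).
#' @export
pair_reads <- function(starts, ends, tlen_tally, paired_count) {
  n <- length(starts)
  max_pairs <- paired_count %/% 2L
  if (n < 2L || max_pairs == 0L) {
    return(list(pairs = data.frame(i = integer(0), j = integer(0),
                                   dist = integer(0)),
                singles = seq_len(n)))
  }
  ord <- order(starts, ends)
  unpaired <- rep(TRUE, n)
  examined <- rep(FALSE, n)
  tv <- tlen_tally$value
  tc <- tlen_tally$count
  pi_ <- integer(0)
  pj <- integer(0)
  pd <- integer(0)
  from_left <- TRUE
  while (length(pi_) < max_pairs) {
    cand <- ord[unpaired[ord] & !examined[ord]]
    if (length(cand) == 0L) break
    r <- if (from_left) cand[1L] else cand[length(cand)]
    examined[r] <- TRUE
    from_left <- !from_left
    others <- which(unpaired)
    others <- others[others != r]
    if (length(others) == 0L) next
    d <- pmax(ends[r], ends[others]) - pmin(starts[r], starts[others])
    o2 <- order(d, decreasing = TRUE)
    hit <- 0L
    for (k in o2) {
      ti <- match(d[k], tv)
      if (!is.na(ti) && tc[ti] > 0L) {
        hit <- k
        break
      }
    }
    if (hit == 0L) next
    q <- others[hit]
    ti <- match(d[hit], tv)
    tc[ti] <- tc[ti] - 1L
    unpaired[c(r, q)] <- FALSE
    lead <- if (starts[r] < starts[q] ||
                (starts[r] == starts[q] && ends[r] <= ends[q])) r else q
    trail <- if (lead == r) q else r
    pi_ <- c(pi_, lead)
    pj <- c(pj, trail)
    pd <- c(pd, d[hit])
  }
  # second pass: random matching of the remainder, up to the paired cap
  remr <- which(unpaired)
  if (length(remr) >= 2L && length(pi_) < max_pairs) {
    remr <- remr[sample.int(length(remr))]
    while (length(remr) >= 2L && length(pi_) < max_pairs) {
      r <- remr[1L]
      q <- remr[2L]
      remr <- remr[-c(1L, 2L)]
      unpaired[c(r, q)] <- FALSE
      d <- max(ends[r], ends[q]) - min(starts[r], starts[q])
      lead <- if (starts[r] < starts[q] ||
                  (starts[r] == starts[q] && ends[r] <= ends[q])) r else q
      trail <- if (lead == r) q else r
      pi_ <- c(pi_, lead)
      pj <- c(pj, trail)
      pd <- c(pd, d)
    }
  }
  list(pairs = data.frame(i = pi_, j = pj, dist = as.integer(pd)),
       singles = which(unpaired))
}

#' Expand one bundle block into alignments
#'
#' Runs read recovery on every bucket, maps recovered intervals back to
#' genomic blocks through the bucket's spanned partitions, then runs one
#' pairing pass over all paired-eligible ends of the bundle against the
#' summed outer-distance tally.
#'
#' @param archive handle from [open_archive()].
#' @param i bundle index.
#' @param seed archive-level seed; the bundle derives its own RNG stream so
#'   expansion is independent of other bundles.
#' @return alignment table sorted by position.
#' @export
expand_bundle <- function(archive, i, seed = 1L) {
  blk <- read_bundle_block(archive, i)
  meta <- archive$bundles[i, ]
  bounds <- c(meta$start, blk$cuts, meta$end)
  partitions <- data.frame(start = bounds[-length(bounds)],
                           end = bounds[-1L])
  blocks <- list()
  nh <- integer(0)
  strand <- character(0)
  eligible <- logical(0)
  tlen_tallies <- list()
  for (b in blk$buckets) {
    geom <- bucket_geometry(b$spanned, partitions)
    reads <- recover_reads(b$coverage, b$length_tally)
    if (nrow(reads)) {
      if (max(geom$segment) == 1L) {
        # contiguous spanned partitions: every read is one block
        gs <- geom$gstart[1L] + reads$start - geom$cstart[1L]
        ge <- gs + (reads$end - reads$start)
        bl <- lapply(seq_len(nrow(reads)), function(k) {
          cbind(start = gs[k], end = ge[k])
        })
      } else {
        bl <- lapply(seq_len(nrow(reads)), function(k) {
          concat_to_blocks(reads$start[k], reads$end[k], geom)
        })
      }
      ordb <- order(vapply(bl, function(m) m[1L, 1L], integer(1)))
      bl <- bl[ordb]
      blocks <- c(blocks, bl)
      nh <- c(nh, rep(b$nh, length(bl)))
      strand <- c(strand, rep(b$strand, length(bl)))
      el <- rep(FALSE, length(bl))
      el[seq_len(min(b$paired_count, length(bl)))] <- TRUE
      eligible <- c(eligible, el)
    }
    tlen_tallies[[length(tlen_tallies) + 1L]] <- b$tlen_tally
  }
  nr <- length(blocks)
  if (nr == 0L) return(empty_alignment_table())
  gstart <- vapply(blocks, function(m) m[1L, 1L], integer(1))
  gend <- vapply(blocks, function(m) m[nrow(m), 2L], integer(1))
  glen <- vapply(blocks, function(m) sum(m[, 2L] - m[, 1L]), integer(1))
  tt <- do.call(tally_merge, tlen_tallies)

  paired <- rep(FALSE, nr)
  pair_id <- rep(NA_integer_, nr)
  mate_chrom <- rep(NA_character_, nr)
  mate_start <- rep(NA_integer_, nr)
  tlen <- rep(0L, nr)
  eidx <- which(eligible)
  if (length(eidx) >= 2L) {
    pr <- with_seed(derive_seed(seed, i), {
      pair_reads(gstart[eidx], gend[eidx], tt, length(eidx))
    })
    if (nrow(pr$pairs)) {
      for (k in seq_len(nrow(pr$pairs))) {
        a <- eidx[pr$pairs$i[k]]
        b <- eidx[pr$pairs$j[k]]
        paired[c(a, b)] <- TRUE
        pair_id[c(a, b)] <- k
        mate_chrom[c(a, b)] <- meta$chrom
        mate_start[a] <- gstart[b]
        mate_start[b] <- gstart[a]
        tlen[a] <- pr$pairs$dist[k]
        tlen[b] <- -pr$pairs$dist[k]
      }
    }
  }
  out <- alignment_table(
    chrom = rep(meta$chrom, nr), start = gstart, blocks = blocks,
    length = glen, strand = strand, nh = nh, paired = paired,
    mate_chrom = mate_chrom, mate_start = mate_start, tlen = tlen,
    pair_id = pair_id
  )
  out <- out[order(out$start, out$end), ]
  rownames(out) <- NULL
  out
}

#' Expand the unbundled section into paired alignments
#'
#' @param archive handle from [open_archive()].
#' @param seed archive-level seed.
#' @param chunk_sel optional integer vector of chunk indices (default: all).
#' @return alignment table of reconstructed cross-bundle pairs.
#' @export
expand_unbundled <- function(archive, seed = 1L, chunk_sel = NULL) {
  if (is.null(chunk_sel)) chunk_sel <- seq_len(nrow(archive$chunks))
  nb <- nrow(archive$bundles)
  out <- list()
  for (ci in chunk_sel) {
    buckets <- read_unbundled_chunk(archive, ci)
    res <- with_seed(derive_seed(seed, nb + ci), {
      lapply(buckets, function(u) expand_unbundled_bucket(archive, u))
    })
    out <- c(out, res)
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0L) return(empty_alignment_table())
  rbind_alignment_tables(out)
}

expand_unbundled_bucket <- function(archive, u) {
  lgeom <- segment_geometry(u$left$iv_start, u$left$iv_end)
  rgeom <- segment_geometry(u$right$iv_start, u$right$iv_end)
  llen <- sum(lgeom$cend - lgeom$cstart)
  cov <- rle_decode(u$coverage)
  lcov <- cov[seq_len(llen)]
  rcov <- cov[(llen + 1L):length(cov)]
  lreads <- recover_reads(rle_encode(lcov), u$length_tally)
  tally2 <- u$length_tally
  if (nrow(lreads)) {
    used <- tally_new(lreads$end - lreads$start)
    m <- match(used$value, tally2$value)
    ok <- !is.na(m)
    tally2$count[m[ok]] <- pmax(0L, tally2$count[m[ok]] - used$count[ok])
    tally2 <- tally2[tally2$count > 0L, , drop = FALSE]
  }
  if (nrow(tally2) == 0L) tally2 <- u$length_tally
  rreads <- recover_reads(rle_encode(rcov), tally2)
  np <- min(u$n_pairs, nrow(lreads), nrow(rreads))
  if (np == 0L) return(NULL)
  lblocks <- lapply(seq_len(nrow(lreads)), function(k) {
    concat_to_blocks(lreads$start[k], lreads$end[k], lgeom)
  })
  rblocks <- lapply(seq_len(nrow(rreads)), function(k) {
    concat_to_blocks(rreads$start[k], rreads$end[k], rgeom)
  })
  lchrom <- archive$chroms$name[u$chrom_left]
  rchrom <- archive$chroms$name[u$chrom_right]
  ls <- vapply(lblocks, function(m) m[1L, 1L], integer(1))
  le <- vapply(lblocks, function(m) m[nrow(m), 2L], integer(1))
  rstt <- vapply(rblocks, function(m) m[1L, 1L], integer(1))
  ren <- vapply(rblocks, function(m) m[nrow(m), 2L], integer(1))
  lord <- order(ls, le)
  rord <- order(rstt, ren)
  # same-chromosome distant pairs: consume the outer-distance tally,
  # most-distant-first; cross-chromosome pairs match in positional order
  if (lchrom == rchrom && nrow(u$tlen_tally)) {
    tv <- u$tlen_tally$value
    tc <- u$tlen_tally$count
    lfree <- lord
    rfree <- rord
    li <- integer(0)
    ri <- integer(0)
    for (a in lfree) {
      if (length(rfree) == 0L) break
      d <- ren[rfree] - ls[a]
      o2 <- order(d, decreasing = TRUE)
      hit <- 0L
      for (k in o2) {
        ti <- match(d[k], tv)
        if (!is.na(ti) && tc[ti] > 0L) {
          hit <- k
          break
        }
      }
      if (hit == 0L) hit <- o2[length(o2)]  # fall back to nearest
      ti <- match(d[hit], tv)
      if (!is.na(ti) && tc[ti] > 0L) tc[ti] <- tc[ti] - 1L
      li <- c(li, a)
      ri <- c(ri, rfree[hit])
      rfree <- rfree[rfree != rfree[hit]]
      if (length(li) == np) break
    }
  } else {
    li <- lord[seq_len(np)]
    ri <- rord[seq_len(np)]
  }
  k <- length(li)
  same <- lchrom == rchrom
  dist <- if (same) as.integer(ren[ri] - ls[li]) else rep(0L, k)
  alignment_table(
    chrom = c(rep(lchrom, k), rep(rchrom, k)),
    start = c(ls[li], rstt[ri]),
    blocks = c(lblocks[li], rblocks[ri]),
    length = c(le[li] - ls[li], ren[ri] - rstt[ri]),
    strand = c(rep(u$left$strand, k), rep(u$right$strand, k)),
    nh = c(rep(u$left$nh, k), rep(u$right$nh, k)),
    paired = rep(TRUE, 2L * k),
    mate_chrom = c(rep(rchrom, k), rep(lchrom, k)),
    mate_start = c(rstt[ri], ls[li]),
    tlen = c(dist, -dist),
    pair_id = c(seq_len(k), seq_len(k))
  )
}

# rbind alignment tables, renumbering pair ids to stay unique
rbind_alignment_tables <- function(tables) {
  tables <- tables[vapply(tables, nrow, integer(1)) > 0L]
  if (length(tables) == 0L) return(empty_alignment_table())
  offset <- 0L
  for (k in seq_along(tables)) {
    pid <- tables[[k]]$pair_id
    has <- !is.na(pid)
    if (any(has)) {
      tables[[k]]$pair_id[has] <- pid[has] + offset
      offset <- offset + max(pid[has])
    }
  }
  out <- do.call(rbind, tables)
  rownames(out) <- NULL
  class(out) <- c("alignment_table", "data.frame")
  out
}
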