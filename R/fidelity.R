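# Fidelity metrics: how much does lossy compression shuffle the data?
# Alignment-level precision/recall (ends or pairs), exon- and
# transcript-level similarity, coverage-weighted transcriptome precision /
# recall, and outer-distance distribution ratios.

#' Score two exons by boundary agreement
#'
#' `1 - min(|x2 - x1|, k)/(2k) - min(|y2 - y1|, k)/(2k)`: each boundary
#' offset costs up to one half, saturating at `k` bases.
#'
#' @param e1,e2 numeric length-2 vectors `(start, end)`.
#' @param k offset threshold in bases (default 10).
#' @return score in \[0, 1\]; 1 for identical exons, 0 when both offsets
#'   reach `k`.
#' @export
exon_score <- function(e1, e2, k = 10) {
  stopifnot(e1[1] < e1[2], e2[1] < e2[2], k >= 1)
  1 - min(abs(e2[1] - e1[1]), k) / (2 * k) -
    min(abs(e2[2] - e1[2]), k) / (2 * k)
}

#' Build a transcript object
#'
#' @param id transcript identifier.
#' @param chrom chromosome.
#' @param strand "+", "-" or "*".
#' @param exons 2-column matrix of sorted, non-overlapping exon intervals.
#' @param coverage non-negative abundance weight.
#' @return list of class `transcript`.
#' @export
transcript <- function(id, chrom, strand, exons, coverage = 1) {
  exons <- matrix(as.numeric(exons), ncol = 2L,
                  dimnames = list(NULL, c("start", "end")))
  stopifnot(all(exons[, 1L] < exons[, 2L]))
  if (nrow(exons) > 1L) {
    stopifnot(!is.unsorted(exons[, 1L]),
              all(exons[-1L, 1L] >= exons[-nrow(exons), 2L]))
  }
  structure(list(id = id, chrom = chrom, strand = strand, exons = exons,
                 coverage = coverage), class = "transcript")
}

#' Score two transcripts by order-preserving exon matching
#'
#' Exons of the two transcripts are matched one-to-one, monotone in exon
#' order, maximizing the summed [exon_score()]; the total is divided by the
#' larger exon count so the score is 1 exactly when the exon lists are
#' identical. Transcripts on different chromosomes, or on opposite known
#' strands, score 0.
#'
#' @param t1,t2 `transcript` objects.
#' @param k exon boundary offset threshold.
#' @return score in \[0, 1\].
#' @export
transcript_score <- function(t1, t2, k = 10) {
  if (t1$chrom != t2$chrom) return(0)
  if (t1$strand != "*" && t2$strand != "*" && t1$strand != t2$strand) {
    return(0)
  }
  n1 <- nrow(t1$exons)
  n2 <- nrow(t2$exons)
  # weighted-LCS dynamic program over monotone one-to-one assignments
  dp <- matrix(0, n1 + 1L, n2 + 1L)
  for (i in seq_len(n1)) {
    for (j in seq_len(n2)) {
      s <- exon_score(t1$exons[i, ], t2$exons[j, ], k)
      dp[i + 1L, j + 1L] <- max(dp[i, j + 1L], dp[i + 1L, j], dp[i, j] + s)
    }
  }
  dp[n1 + 1L, n2 + 1L] / max(n1, n2)
}

.check_weighted <- function(txs, what) {
  if (length(txs) == 0L) {
    stop(what, " transcriptome is empty: weighted metric undefined")
  }
}

#' Coverage-weighted transcriptome precision and recall
#'
#' Precision scores every assembled transcript against its best match in the
#' reference, weighted by its coverage; recall scores every reference
#' transcript against its best match in the assembly, weighted by true
#' coverage. Both are normalized by total weight, so a transcriptome scored
#' against itself gives exactly 1.
#'
#' @param t_hat list of `transcript` objects (assembled).
#' @param t_ref list of `transcript` objects (reference).
#' @param k exon boundary offset threshold.
#' @return numeric scalar in \[0, 1\].
#' @export
weighted_precision <- function(t_hat, t_ref, k = 10) {
  .check_weighted(t_hat, "assembled")
  .check_weighted(t_ref, "reference")
  w <- vapply(t_hat, `[[`, numeric(1), "coverage")
  best <- vapply(t_hat, function(th) {
    max(vapply(t_ref, function(tr) transcript_score(th, tr, k), numeric(1)))
  }, numeric(1))
  sum(best * w) / sum(w)
}

#' @rdname weighted_precision
#' @export
weighted_recall <- function(t_ref, t_hat, k = 10) {
  .check_weighted(t_ref, "reference")
  .check_weighted(t_hat, "assembled")
  w <- vapply(t_ref, `[[`, numeric(1), "coverage")
  best <- vapply(t_ref, function(tr) {
    max(vapply(t_hat, function(th) transcript_score(tr, th, k), numeric(1)))
  }, numeric(1))
  sum(best * w) / sum(w)
}

# match key of one alignment end: position + all overlapped splice junctions
.end_keys <- function(alignments) {
  n <- nrow(alignments)
  jstr <- character(n)
  spliced <- which(vapply(alignments$blocks, nrow, integer(1)) > 1L)
  if (length(spliced)) {
    jstr[spliced] <- vapply(spliced, function(i) {
      j <- blocks_junctions(alignments$blocks[[i]])
      paste(j[, "donor"], j[, "acceptor"], sep = "-", collapse = ";")
    }, "")
  }
  paste(alignments$chrom, alignments$start, jstr, sep = ":")
}

.pair_keys <- function(alignments) {
  a <- alignments[alignments$paired & !is.na(alignments$pair_id), ]
  if (nrow(a) == 0L) return(character(0))
  ek <- .end_keys(a)
  unlist(lapply(split(seq_len(nrow(a)), a$pair_id), function(rows) {
    if (length(rows) != 2L) return(NULL)
    paste(sort(ek[rows]), collapse = "~")
  }), use.names = FALSE)
}

#' Alignment-level precision and recall of a lossy round trip
#'
#' In `ends` mode each end matches when chromosome, start position and all
#' overlapped splice junctions are identical; matching is multiset
#' intersection, so an alignment matches at most one counterpart. In `pairs`
#' mode both ends of a pair must match their counterparts.
#'
#' @param original,compressed alignment tables from the same reference.
#' @param mode `"ends"` or `"pairs"`.
#' @return named numeric vector `precision`, `recall`.
#' @export
alignment_pr <- function(original, compressed, mode = c("ends", "pairs")) {
  mode <- match.arg(mode)
  ko <- if (mode == "ends") .end_keys(original) else .pair_keys(original)
  kc <- if (mode == "ends") .end_keys(compressed) else .pair_keys(compressed)
  to <- table(ko)
  tc <- table(kc)
  common <- intersect(names(to), names(tc))
  matched <- sum(pmin(to[common], tc[common]))
  c(precision = matched / length(kc), recall = matched / length(ko))
}

#' Outer-distance frequency ratios, compressed over original
#'
#' @param original,compressed outer-distance tallies.
#' @return data.frame `value`, `original`, `compressed`, `ratio`; a distance
#'   present only in the compressed tally has ratio `Inf`.
#' @export
tlen_ratio <- function(original, compressed) {
  stopifnot(nrow(original) > 0L || nrow(compressed) > 0L)
  vals <- sort(union(original$value, compressed$value))
  co <- original$count[match(vals, original$value)]
  cc <- compressed$count[match(vals, compressed$value)]
  co[is.na(co)] <- 0L
  cc[is.na(cc)] <- 0L
  data.frame(value = vals, original = co, compressed = cc,
             ratio = ifelse(co == 0L, Inf, cc / co))
}

#' Read transcript structures from a GTF file
#'
#' Exon features are grouped by `transcript_id`; weights default to 1 and
#' can be attached from a two-column table via `weights`.
#'
#' @param path GTF file.
#' @param weights optional data.frame (`transcript_id`, `coverage`).
#' @return list of `transcript` objects.
#' @export
read_gtf_transcripts <- function(path, weights = NULL) {
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type == "exon"]
  ids <- as.character(gr$transcript_id)
  bioc <- function(fn) getExportedValue("BiocGenerics", fn)
  st <- bioc("start")
  en <- bioc("end")
  lapply(split(seq_along(gr), ids), function(idx) {
    g <- gr[idx]
    o <- order(st(g))
    id <- ids[idx[1L]]
    w <- 1
    if (!is.null(weights)) {
      m <- match(id, weights$transcript_id)
      if (!is.na(m)) w <- weights$coverage[m]
    }
    transcript(
      id = id,
      chrom = as.character(getExportedValue("GenomeInfoDb", "seqnames")(g))[1L],
      strand = as.character(bioc("strand")(g))[1L],
      # GTF is 1-based closed; internal convention is 0-based half-open
      exons = cbind(st(g)[o] - 1L, en(g)[o]),
      coverage = w
    )
  })
}
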