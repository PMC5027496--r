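# Bundling: group sorted alignments into gene-scale bundles (a new bundle
# opens when the next alignment starts more than `gap` bases past the running
# end of the current one), and classify/handle paired-end alignments that do
# not fit the bundling scheme.

BUNDLE_GAP <- 50L

#' Partition sorted alignments into bundles
#'
#' As sorted alignments are scanned, an alignment starting within 50 bases of
#' the running end of the current bundle joins it; otherwise a new bundle
#' opens. Spliced alignments extend the running end across their introns.
#'
#' @param alignments alignment table, coordinate-sorted.
#' @param gap maximum start-to-end gap for joining the current bundle.
#' @return list with `bundles` (data.frame `chrom`, `start`, `end`, one row
#'   per bundle in genomic order) and `bundle_of` (integer vector mapping each
#'   alignment row to its bundle index).
#' @export
build_bundles <- function(alignments, gap = BUNDLE_GAP) {
  a <- alignments
  n <- nrow(a)
  if (n == 0L) {
    return(list(
      bundles = data.frame(chrom = character(0), start = integer(0),
                           end = integer(0), stringsAsFactors = FALSE),
      bundle_of = integer(0)
    ))
  }
  bundle_of <- integer(n)
  nb <- 0L
  chrom_runs <- rle(a$chrom)
  offset <- 0L
  for (r in seq_along(chrom_runs$lengths)) {
    idx <- offset + seq_len(chrom_runs$lengths[r])
    offset <- offset + chrom_runs$lengths[r]
    s <- a$start[idx]
    e <- cummax(a$end[idx])
    newb <- c(TRUE, s[-1L] > e[-length(e)] + gap)
    bundle_of[idx] <- nb + cumsum(newb)
    nb <- nb + sum(newb)
  }
  spans <- data.frame(
    chrom = a$chrom[!duplicated(bundle_of)],
    start = as.integer(tapply(a$start, bundle_of, min)),
    end = as.integer(tapply(a$end, bundle_of, max)),
    stringsAsFactors = FALSE
  )
  rownames(spans) <- NULL
  list(bundles = spans, bundle_of = bundle_of)
}

#' Classify one paired-end alignment pair
#'
#' Categories of pairs that do not fit bundling: `cross_chromosome` (ends on
#' different chromosomes), `intron_nested` (one end lies entirely inside an
#' intron of the other), `distant` (ends resolve to different bundles on one
#' chromosome), `discordant_strand` (ends carry opposite known strands).
#'
#' @param a,b single-row alignment tables, the two ends of one pair.
#' @param bundle_a,bundle_b bundle indices of the two ends.
#' @return category string, or `NA_character_` for an ordinary pair.
#' @export
classify_pair <- function(a, b, bundle_a, bundle_b) {
  if (a$chrom != b$chrom) return("cross_chromosome")
  if (nested_in_intron(b$start, b$end, a$blocks[[1L]]) ||
      nested_in_intron(a$start, a$end, b$blocks[[1L]])) {
    return("intron_nested")
  }
  if (bundle_a != bundle_b) return("distant")
  if (a$strand != "*" && b$strand != "*" && a$strand != b$strand) {
    return("discordant_strand")
  }
  NA_character_
}

nested_in_intron <- function(start, end, blocks) {
  nb <- nrow(blocks)
  if (nb < 2L) return(FALSE)
  any(start >= blocks[-nb, 2L] & end <= blocks[-1L, 1L])
}

#' Classify and handle all special pairs before compression
#'
#' Intron-nested pairs become two unpaired reads unless `preserve_nested`.
#' Cross-chromosome and distant pairs are pulled out of the bundled set for
#' the unbundled archive section. Discordant-strand pairs have one end,
#' chosen by the seeded RNG, harmonized to the other's strand; with
#' `split_discordant` they become unpaired instead.
#'
#' @param alignments alignment table (pairs linked by `pair_id`).
#' @param bundle_of bundle index per alignment row.
#' @param preserve_nested keep intron-nested pairs paired.
#' @param split_discordant split discordant-strand pairs into unpaired reads.
#' @return list with `alignments` (modified table, unbundled rows removed),
#'   `bundle_of` (matching subset), and `unbundled` (data.frame of removed
#'   pairs: row indices into the original table are not kept; the rows
#'   themselves are, as `left`/`right` single-row tables, with `category` and
#'   `bundle_left`/`bundle_right`).
#' @export
handle_special_pairs <- function(alignments, bundle_of,
                                 preserve_nested = FALSE,
                                 split_discordant = FALSE) {
  a <- alignments
  drop <- logical(nrow(a))
  unb <- list()
  if (any(a$paired)) {
    p <- which(a$paired)
    ord <- p[order(a$pair_id[p], a$start[p], a$end[p])]
    i1 <- ord[c(TRUE, FALSE)]
    i2 <- ord[c(FALSE, TRUE)]
    # ordinary pairs (same chromosome & bundle, compatible strands, both
    # unspliced) can never be special; classify only the rest
    nbl <- vapply(a$blocks, nrow, integer(1))
    special <- a$chrom[i1] != a$chrom[i2] |
      bundle_of[i1] != bundle_of[i2] |
      (a$strand[i1] != "*" & a$strand[i2] != "*" &
         a$strand[i1] != a$strand[i2]) |
      nbl[i1] > 1L | nbl[i2] > 1L
    for (k in which(special)) {
      i <- i1[k]
      j <- i2[k]
      cat_ <- classify_pair(a[i, ], a[j, ], bundle_of[i], bundle_of[j])
      if (is.na(cat_)) next
      if (cat_ == "intron_nested") {
        if (!preserve_nested) {
          a$paired[c(i, j)] <- FALSE
          a$pair_id[c(i, j)] <- NA_integer_
          a$mate_chrom[c(i, j)] <- NA_character_
          a$mate_start[c(i, j)] <- NA_integer_
          a$tlen[c(i, j)] <- 0L
        }
      } else if (cat_ == "discordant_strand") {
        if (split_discordant) {
          a$paired[c(i, j)] <- FALSE
          a$pair_id[c(i, j)] <- NA_integer_
          a$mate_chrom[c(i, j)] <- NA_character_
          a$mate_start[c(i, j)] <- NA_integer_
          a$tlen[c(i, j)] <- 0L
        } else {
          flip <- if (stats::runif(1) < 0.5) i else j
          keep_ <- if (flip == i) j else i
          a$strand[flip] <- a$strand[keep_]
        }
      } else {
        # cross_chromosome / distant: route to the unbundled section
        lo <- if (a$chrom[i] < a$chrom[j] ||
                  (a$chrom[i] == a$chrom[j] && a$start[i] <= a$start[j])) {
          c(i, j)
        } else c(j, i)
        unb[[length(unb) + 1L]] <- list(
          left = a[lo[1L], ], right = a[lo[2L], ], category = cat_,
          bundle_left = bundle_of[lo[1L]], bundle_right = bundle_of[lo[2L]]
        )
        drop[c(i, j)] <- TRUE
      }
    }
  }
  list(
    alignments = a[!drop, ],
    bundle_of = bundle_of[!drop],
    unbundled = unb
  )
}
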