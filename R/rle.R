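# Run-length coding of coverage vectors: the storage form of per-bucket
# depth. Canonical (maximal) runs, via base rle().

#' Run-length encode a depth vector
#'
#' @param depths non-negative integer vector of per-base depths.
#' @return list of class `coverage_rle` with `values` (depths) and `lengths`
#'   (run lengths); adjacent runs always have distinct depths.
#' @export
rle_encode <- function(depths) {
  if (length(depths) && (anyNA(depths) || any(depths < 0))) {
    stop("coverage depths must be non-negative")
  }
  r <- rle(as.integer(depths))
  structure(list(values = r$values, lengths = r$lengths),
            class = "coverage_rle")
}

#' Expand a run-length encoded coverage vector
#'
#' Exact inverse of [rle_encode()].
#' @param cv a `coverage_rle` object.
#' @return integer vector of per-base depths.
#' @export
rle_decode <- function(cv) {
  rep.int(cv$values, cv$lengths)
}

#' @export
print.coverage_rle <- function(x, ...) {
  cat("coverage_rle:", length(x$values), "runs,",
      sum(x$lengths), "bases, total depth", sum(x$values * x$lengths), "\n")
  invisible(x)
}
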