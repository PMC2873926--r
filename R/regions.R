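#' Genomic target region with an optional probe-coverage mask
#'
#' Coordinates are 0-based, half-open (BED convention).  `covered` holds the
#' probed/callable sub-intervals; positions outside them carry no genotype
#' calls.  The region center, used by the central masking scans, is the floor
#' of the midpoint.
#'
#' @param id Region label (e.g. `"harseq21"`).
#' @param chrom Chromosome label.
#' @param start,end Region bounds in bp, `start < end`.
#' @param covered Optional two-column matrix or data frame of covered
#'   sub-interval `(start, end)` pairs; defaults to the whole region.
#'   Intervals must be disjoint, sorted, and lie within `[start, end)`.
#' @return An object of class `region`.
#' @export
region <- function(id, chrom, start, end, covered = NULL) {
  start <- as.numeric(start)
  end <- as.numeric(end)
  if (start >= end) stop("region start must be < end")
  if (is.null(covered)) {
    covered <- cbind(start, end)
  } else {
    covered <- as.matrix(covered[, 1:2, drop = FALSE])
    storage.mode(covered) <- "numeric"
    covered <- covered[order(covered[, 1]), , drop = FALSE]
    if (any(covered[, 1] >= covered[, 2])) {
      stop("covered intervals must have start < end")
    }
    if (any(covered[, 1] < start) || any(covered[, 2] > end)) {
      stop("covered intervals must lie within the region")
    }
    if (nrow(covered) > 1 &&
        any(covered[-1, 1] < covered[-nrow(covered), 2])) {
      stop("covered intervals must be disjoint")
    }
  }
  dimnames(covered) <- list(NULL, c("start", "end"))
  structure(list(id = as.character(id), chrom = as.character(chrom),
                 start = start, end = end, covered = covered),
            class = "region")
}

#' @export
print.region <- function(x, ...) {
  cat(sprintf("region %s  %s:%d-%d (%d bp, %.1f%% covered in %d intervals)\n",
              x$id, x$chrom, x$start, x$end, region_length(x),
              100 * covered_fraction(x), nrow(x$covered)))
  invisible(x)
}

#' @rdname region
#' @param x A `region`.
#' @export
region_center <- function(x) floor((x$start + x$end) / 2)

#' @rdname region
#' @export
region_length <- function(x) as.integer(x$end - x$start)

#' @rdname region
#' @export
covered_fraction <- function(x) {
  sum(x$covered[, 2] - x$covered[, 1]) / (x$end - x$start)
}

#' Are positions inside the covered mask of a region?
#' @param x A `region`.
#' @param pos Numeric vector of 0-based positions.
#' @return Logical vector.
#' @export
in_covered <- function(x, pos) {
  stopifnot(inherits(x, "region"))
  out <- rep(FALSE, length(pos))
  for (r in seq_len(nrow(x$covered))) {
    out <- out | (pos >= x$covered[r, 1] & pos < x$covered[r, 2])
  }
  out
}
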