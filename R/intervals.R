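#' Do two intervals overlap?
#'
#' Half-open semantics: intervals sharing only an endpoint do not overlap.
#'
#' @param a,b Lists or one-row data frames with `chrom`, `start`, `end`.
#' @return `TRUE` iff same chromosome and at least 1 bp is shared.
#' @export
interval_overlaps <- function(a, b) {
  identical(as.character(a$chrom), as.character(b$chrom)) &&
    a$start < b$end && b$start < a$end
}

#' Interval midpoint
#'
#' `floor((start + end) / 2)`; the fixed reference point used for all
#' peak-to-TSS distance and window computations.
#'
#' @param start,end Numeric vectors (0-based half-open coordinates).
#' @return Numeric vector of midpoints.
#' @export
interval_midpoint <- function(start, end) floor((start + end) / 2)

#' Strand-aware signed distance from a point to a TSS
#'
#' Negative = upstream of the TSS, positive = downstream, 0 = at the TSS.
#' For a plus-strand gene the distance is `point - tss`; for a minus-strand
#' gene it is `tss - point`.
#'
#' @param point Numeric vector of 0-based positions.
#' @param gene A single gene record (list or one-row data frame with
#'   `chrom`, `strand`, `tss`).
#' @param chrom Optional chromosome of `point`; checked against the gene's
#'   when supplied.
#' @return Numeric vector of signed distances in bp.
#' @export
signed_tss_distance <- function(point, gene, chrom = NULL) {
  if (!is.null(chrom) && any(chrom != gene$chrom)) {
    stop("point chromosome does not match gene chromosome")
  }
  if (gene$strand == "+") point - gene$tss else gene$tss - point
}

peaks_to_granges <- function(peaks) {
  GenomicRanges::GRanges(
    seqnames = peaks$chrom,
    ranges = IRanges::IRanges(start = peaks$start + 1L, end = peaks$end)
  )
}

#' Count query intervals overlapped by a subject set
#'
#' Each query interval is flagged at most once no matter how many subject
#' intervals touch it (>= 1 bp shared, half-open semantics).
#'
#' @param query,subject [peak_set()] objects (or data frames with
#'   `chrom`/`start`/`end`).
#' @return List with `count` (number of flagged query intervals) and
#'   `flags` (logical vector along `query`).
#' @export
count_overlapping <- function(query, subject) {
  if (nrow(query) == 0 || nrow(subject) == 0) {
    return(list(count = 0L, flags = rep(FALSE, nrow(query))))
  }
  hits <- GenomicRanges::findOverlaps(
    peaks_to_granges(query), peaks_to_granges(subject),
    minoverlap = 1L, ignore.strand = TRUE
  )
  flags <- rep(FALSE, nrow(query))
  flags[unique(S4Vectors::queryHits(hits))] <- TRUE
  list(count = sum(flags), flags = flags)
}
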