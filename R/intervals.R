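#' Interval sets (0-based, half-open)
#'
#' A thin container for genomic intervals used for repeat annotations and
#' capture-target regions. Intervals are stored 0-based half-open and kept
#' sorted by (contig, start). Overlap queries are delegated to
#' \pkg{GenomicRanges}.
#'
#' @param contig character vector of contig names.
#' @param start0 integer vector, 0-based inclusive starts.
#' @param end0 integer vector, 0-based exclusive ends; must satisfy
#'   `start0 < end0`.
#' @return An object of class `interval_set`: a data.frame with columns
#'   `contig`, `start0`, `end0`, sorted by contig then start.
#' @examples
#' iv <- interval_set("chr1", 10, 20)
#' interval_width(iv)
#' @export
interval_set <- function(contig = character(), start0 = integer(), end0 = integer()) {
  stopifnot(length(contig) == length(start0), length(start0) == length(end0))
  start0 <- as.integer(start0)
  end0 <- as.integer(end0)
  if (any(start0 >= end0)) stop("interval_set: start0 must be < end0")
  if (any(start0 < 0)) stop("interval_set: negative start")
  df <- data.frame(contig = as.character(contig), start0 = start0, end0 = end0,
                   stringsAsFactors = FALSE)
  df <- df[order(df$contig, df$start0, df$end0), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("interval_set", "data.frame")
  df
}

#' @rdname interval_set
#' @param x an `interval_set`.
#' @export
interval_width <- function(x) x$end0 - x$start0

# GRanges view of an interval_set (1-based closed, as GenomicRanges expects)
as_granges <- function(x) {
  GenomicRanges::GRanges(
    seqnames = x$contig,
    ranges = IRanges::IRanges(start = x$start0 + 1L, end = x$end0)
  )
}

#' Point-overlap query against an interval set
#'
#' Tests, for each query point, whether it falls inside any interval
#' (half-open: a point equal to an interval's `end0` does not overlap).
#'
#' @param x an `interval_set`.
#' @param contig character vector of query contigs.
#' @param pos0 integer vector of query positions (0-based).
#' @return logical vector, one element per query.
#' @export
interval_overlaps_point <- function(x, contig, pos0) {
  stopifnot(length(contig) == length(pos0))
  if (nrow(x) == 0L || length(pos0) == 0L) return(rep(FALSE, length(pos0)))
  q <- GenomicRanges::GRanges(contig, IRanges::IRanges(pos0 + 1L, pos0 + 1L))
  # queries on contigs absent from the set are legal (they just miss)
  suppressWarnings(IRanges::overlapsAny(q, as_granges(x)))
}

#' Interval-overlap query (any shared base)
#'
#' @param x an `interval_set`.
#' @param contig,start0,end0 query intervals, 0-based half-open.
#' @return logical vector, one element per query.
#' @export
interval_overlaps_range <- function(x, contig, start0, end0) {
  n <- length(contig)
  stopifnot(length(start0) == n, length(end0) == n)
  if (nrow(x) == 0L || n == 0L) return(rep(FALSE, n))
  q <- GenomicRanges::GRanges(contig, IRanges::IRanges(start0 + 1L, end0))
  suppressWarnings(IRanges::overlapsAny(q, as_granges(x)))
}

#' Merge overlapping or adjacent intervals
#'
#' @param x an `interval_set`.
#' @return an `interval_set` with overlapping intervals merged per contig.
#' @export
interval_merge <- function(x) {
  if (nrow(x) == 0L) return(x)
  r <- GenomicRanges::reduce(as_granges(x))
  interval_set(as.character(GenomicRanges::seqnames(r)),
               GenomicRanges::start(r) - 1L,
               GenomicRanges::end(r))
}
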