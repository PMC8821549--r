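#' Genomic interval data frames
#'
#' Throughout the package genomic intervals are plain data frames with at
#' least the columns `chrom` (character), `start` and `end` (integer base
#' offsets, 0-based half-open, BED convention).  `genomic_intervals()`
#' builds and validates such a frame; all interval operations accept any
#' data frame carrying those three columns.
#'
#' @param chrom character vector of chromosome/sequence names.
#' @param start,end integer vectors; `0 <= start < end` per row.
#' @return A data frame with columns `chrom`, `start`, `end`.
#' @examples
#' genomic_intervals("chr1", 100, 200)
#' @export
genomic_intervals <- function(chrom, start, end) {
  x <- data.frame(chrom = as.character(chrom),
                  start = as.integer(start),
                  end   = as.integer(end),
                  stringsAsFactors = FALSE)
  validate_intervals(x)
  x
}

validate_intervals <- function(x, what = "interval") {
  if (!all(c("chrom", "start", "end") %in% names(x)))
    stop(what, " table must have columns chrom, start, end", call. = FALSE)
  if (nrow(x) == 0) return(invisible(x))
  if (any(is.na(x$start)) || any(is.na(x$end)))
    stop(what, " coordinates contain missing values", call. = FALSE)
  if (any(x$start < 0))
    stop(what, " start must be >= 0", call. = FALSE)
  bad <- which(x$start >= x$end)
  if (length(bad))
    stop(what, " must satisfy start < end (half-open); offending row(s): ",
         paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
  invisible(x)
}

# internal: 0-based half-open data frame -> GRanges (1-based closed)
gi_to_gr <- function(x, seqlevels = NULL) {
  if (is.null(seqlevels)) seqlevels <- sort(unique(as.character(x$chrom)))
  GenomicRanges::GRanges(
    seqnames = factor(as.character(x$chrom), levels = seqlevels),
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end))
}

# internal: GRanges -> 0-based half-open data frame, sorted
gr_to_gi <- function(gr) {
  x <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                  start = GenomicRanges::start(gr) - 1L,
                  end   = GenomicRanges::end(gr),
                  stringsAsFactors = FALSE)
  sort_intervals(x)
}

sort_intervals <- function(x) {
  x <- x[order(x$chrom, x$start, x$end), , drop = FALSE]
  rownames(x) <- NULL
  x
}

#' Merge overlapping or nearby intervals
#'
#' Collapses a set of intervals into maximal non-overlapping intervals per
#' chromosome.  Under the half-open convention, book-ended intervals
#' (`[a,b)` and `[b,c)`) merge at `max_gap = 0`; more generally two
#' intervals merge when the number of uncovered bases between them is at
#' most `max_gap`.  With `max_gap = 0` the total number of covered bases is
#' unchanged.
#'
#' @param intervals data frame with `chrom`, `start`, `end`.
#' @param max_gap non-negative integer; gaps of at most this many bases are
#'   closed.
#' @return Sorted data frame of pairwise non-overlapping intervals.
#' @examples
#' merge_intervals(genomic_intervals("chr1", c(100, 150), c(200, 250)))
#' @export
merge_intervals <- function(intervals, max_gap = 0L) {
  if (length(max_gap) != 1L || is.na(max_gap) || max_gap < 0)
    stop("max_gap must be a single non-negative integer", call. = FALSE)
  validate_intervals(intervals)
  if (nrow(intervals) == 0)
    return(genomic_intervals(character(), integer(), integer()))
  gr <- GenomicRanges::reduce(gi_to_gr(intervals),
                              min.gapwidth = as.integer(max_gap) + 1L)
  gr_to_gi(gr)
}

# internal: per-chromosome complement of intervals within [0, size)
complement_intervals <- function(intervals, chrom_sizes) {
  out <- lapply(names(chrom_sizes), function(ch) {
    size <- chrom_sizes[[ch]]
    sub <- intervals[intervals$chrom == ch, , drop = FALSE]
    if (nrow(sub) == 0)
      return(data.frame(chrom = ch, start = 0L, end = as.integer(size)))
    m <- merge_intervals(sub)
    starts <- c(0L, m$end)
    ends <- c(m$start, as.integer(size))
    keep <- starts < ends
    data.frame(chrom = ch, start = starts[keep], end = ends[keep])
  })
  sort_intervals(do.call(rbind, out))
}

round_half_up <- function(x) floor(x + 0.5)
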