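#' Replicate-consensus peaks by per-base intersection
#'
#' A consensus binding region is a maximal run of bases covered by at
#' least one peak in *every* replicate of a sample — the formalisation of
#' peaks "present in the same locations in all replicates".  The consensus
#' interval is the mutually covered region (not any single replicate's
#' interval); its height is the minimum over replicates of the maximum
#' height among that replicate's contributing peaks, a conservative
#' support measure.
#'
#' @param replicate_peaks named list, one peak data frame per replicate
#'   (see [read_peaks()]).  Must be non-empty.
#' @param min_width smallest consensus width retained (bases); default 1,
#'   i.e. any mutually covered run counts.
#' @param sample_id optional sample label stored on the result.
#' @return Object of class `consensus_peaks`: a list with
#'   \describe{
#'     \item{peaks}{data frame `consensus_id`, `chrom`, `start`, `end`,
#'       `height`, `sample_id`, sorted deterministically;}
#'     \item{support}{data frame listing every contributing replicate peak
#'       per consensus region (`consensus_id`, `replicate_id`, `chrom`,
#'       `start`, `end`, `height`);}
#'     \item{n_replicates}{number of replicates intersected.}
#'   }
#' @examples
#' reps <- list(
#'   rep1 = genomic_intervals("chr1", 100, 200),
#'   rep2 = genomic_intervals("chr1", 150, 250),
#'   rep3 = genomic_intervals("chr1", 180, 220))
#' intersect_replicates(reps)$peaks  # one region [180,200)
#' @export
intersect_replicates <- function(replicate_peaks, min_width = 1L,
                                 sample_id = NA_character_) {
  if (!is.list(replicate_peaks) || length(replicate_peaks) == 0)
    stop("replicate_peaks must be a non-empty list of peak tables",
         call. = FALSE)
  if (min_width < 1) stop("min_width must be >= 1", call. = FALSE)
  ids <- names(replicate_peaks)
  if (is.null(ids) || any(!nzchar(ids)))
    ids <- sprintf("rep%d", seq_along(replicate_peaks))
  replicate_peaks <- lapply(replicate_peaks, function(p) {
    validate_intervals(p, "peak")
    if (!"height" %in% names(p)) p$height <- rep(0, nrow(p))
    p
  })
  seqlev <- sort(unique(unlist(lapply(replicate_peaks,
                                      function(p) as.character(p$chrom)))))
  empty <- structure(
    list(peaks = data.frame(consensus_id = character(), chrom = character(),
                            start = integer(), end = integer(),
                            height = numeric(), sample_id = character(),
                            stringsAsFactors = FALSE),
         support = data.frame(consensus_id = character(),
                              replicate_id = character(),
                              chrom = character(), start = integer(),
                              end = integer(), height = numeric(),
                              stringsAsFactors = FALSE),
         sample_id = sample_id, n_replicates = length(replicate_peaks)),
    class = "consensus_peaks")
  if (any(vapply(replicate_peaks, nrow, integer(1)) == 0) ||
      length(seqlev) == 0)
    return(empty)

  grs <- lapply(replicate_peaks, function(p) {
    GenomicRanges::reduce(gi_to_gr(p, seqlevels = seqlev))
  })
  cons <- Reduce(GenomicRanges::intersect, grs)
  cons <- cons[GenomicRanges::width(cons) >= min_width]
  if (length(cons) == 0) return(empty)
  cons <- sort(cons)
  peaks <- gr_to_gi(cons)
  peaks$consensus_id <- sprintf("cons_%05d", seq_len(nrow(peaks)))
  cons_gr <- gi_to_gr(peaks, seqlevels = seqlev)

  support <- list()
  heights <- matrix(NA_real_, nrow = nrow(peaks),
                    ncol = length(replicate_peaks))
  for (j in seq_along(replicate_peaks)) {
    p <- replicate_peaks[[j]]
    hit <- GenomicRanges::findOverlaps(cons_gr, gi_to_gr(p, seqlevels = seqlev))
    qi <- S4Vectors::queryHits(hit)
    si <- S4Vectors::subjectHits(hit)
    support[[j]] <- data.frame(
      consensus_id = peaks$consensus_id[qi],
      replicate_id = ids[j],
      chrom = p$chrom[si], start = p$start[si], end = p$end[si],
      height = p$height[si], stringsAsFactors = FALSE)
    hmax <- tapply(p$height[si], qi, max)
    heights[as.integer(names(hmax)), j] <- hmax
  }
  peaks$height <- apply(heights, 1L, min)
  peaks$sample_id <- sample_id
  support <- do.call(rbind, support)
  support <- support[order(support$consensus_id, support$replicate_id,
                           support$start), , drop = FALSE]
  rownames(support) <- NULL
  structure(list(peaks = peaks[, c("consensus_id", "chrom", "start", "end",
                                   "height", "sample_id")],
                 support = support, sample_id = sample_id,
                 n_replicates = length(replicate_peaks)),
            class = "consensus_peaks")
}

#' @export
print.consensus_peaks <- function(x, ...) {
  cat("Consensus peaks (", x$n_replicates, " replicates",
      if (!is.na(x$sample_id)) paste0(", sample ", x$sample_id), "): ",
      nrow(x$peaks), " regions\n", sep = "")
  if (nrow(x$peaks)) print(utils::head(x$peaks, 10L))
  invisible(x)
}

# internal: accept a consensus_peaks object or a plain interval frame
peak_frame <- function(x) {
  if (inherits(x, "consensus_peaks")) x <- x$peaks
  validate_intervals(x, "peak")
  if (!"consensus_id" %in% names(x)) {
    x <- sort_intervals(x)
    x$consensus_id <- sprintf("peak_%05d", seq_len(nrow(x)))
  }
  x
}

#' Peak-width histogram and sub-500 bp fraction
#'
#' Bins peak widths into `(-Inf, e1), [e1, e2), ..., [ek, Inf)` for the
#' supplied edges, so counts always sum to the number of peaks, and
#' reports the fraction of peaks strictly narrower than 500 bp (ChIP-Seq
#' peaks for sequence-specific factors are typically below that width).
#'
#' @param peaks peak/interval data frame or `consensus_peaks` object.
#' @param bins strictly increasing numeric vector of width bin edges.
#' @return List with `counts` (named integer vector), `fraction_lt_500`,
#'   and `n`.
#' @export
peak_width_summary <- function(peaks, bins = c(100, 200, 500, 1000, 2000)) {
  x <- if (inherits(peaks, "consensus_peaks")) peaks$peaks else peaks
  validate_intervals(x, "peak")
  if (nrow(x) == 0) stop("peak list is empty", call. = FALSE)
  if (length(bins) < 1 || is.unsorted(bins, strictly = TRUE))
    stop("bins must be strictly increasing width edges", call. = FALSE)
  w <- x$end - x$start
  idx <- findInterval(w, bins)  # 0 .. length(bins)
  labs <- c(sprintf("[0,%g)", bins[1]),
            if (length(bins) > 1)
              sprintf("[%g,%g)", bins[-length(bins)], bins[-1]),
            sprintf("[%g,Inf)", bins[length(bins)]))
  counts <- tabulate(idx + 1L, nbins = length(bins) + 1L)
  names(counts) <- labs
  list(counts = counts, fraction_lt_500 = mean(w < 500), n = nrow(x))
}

# internal: BH adjustment on distinct p-values carrying multiplicities,
# equivalent to stats::p.adjust(rep(p, count), "BH") evaluated per value
bh_adjust_weighted <- function(p, count, total = sum(count)) {
  o <- order(p)
  p_s <- p[o]
  cum <- cumsum(count[o])          # largest rank within each tie block
  adj <- p_s * total / cum
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(length(p))
  out[o] <- adj
  out
}

#' Simplified Poisson pileup peak caller
#'
#' Computes per-base fragment coverage, tests each base against a Poisson
#' background whose mean is `background_rate` times the mean fragment
#' length, adjusts the upper-tail probabilities over all genome positions
#' by Benjamini-Hochberg, and keeps bases with adjusted value below
#' `q_cutoff`.  Significant bases are merged (gaps up to `max_gap` closed)
#' and regions narrower than `min_width` are discarded.  Each peak's
#' height is the maximum coverage in the region and its summit the
#' leftmost base attaining it.  This is a deliberately simple caller for
#' synthetic fragment tracks, not a MACS2 replacement (no local lambda,
#' no fragment-size model).
#'
#' @param fragments interval data frame of sequenced fragments.
#' @param genome_lengths named vector of chromosome lengths (bases).
#' @param background_rate expected fragments per base under background
#'   (> 0).
#' @param q_cutoff BH-adjusted significance cutoff (peaks require
#'   adjusted value strictly below it).
#' @param max_gap merge gap between significant runs (bases).
#' @param min_width minimum peak width (bases).
#' @return Peak data frame as from [read_peaks()] with `height` (max
#'   coverage) and `summit_offset` filled in.
#' @export
pileup_call <- function(fragments, genome_lengths, background_rate,
                        q_cutoff = 0.05, max_gap = 50L, min_width = 50L) {
  if (length(genome_lengths) == 0 || any(genome_lengths <= 0))
    stop("genome_lengths must be positive per chromosome", call. = FALSE)
  if (is.null(names(genome_lengths)))
    stop("genome_lengths must be named by chromosome", call. = FALSE)
  if (background_rate <= 0)
    stop("background_rate must be > 0", call. = FALSE)
  validate_intervals(fragments, "fragment")
  if (nrow(fragments) == 0) return(empty_peaks())
  unknown <- setdiff(unique(fragments$chrom), names(genome_lengths))
  if (length(unknown))
    stop("fragments on chromosome(s) absent from genome_lengths: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  if (any(fragments$end > genome_lengths[fragments$chrom]))
    stop("fragment extends beyond chromosome end", call. = FALSE)

  mean_len <- mean(fragments$end - fragments$start)
  lambda <- background_rate * mean_len
  chroms <- names(genome_lengths)

  cov <- lapply(chroms, function(ch) {
    sub <- fragments[fragments$chrom == ch, , drop = FALSE]
    if (nrow(sub) == 0)
      return(S4Vectors::Rle(0L, as.integer(genome_lengths[[ch]])))
    IRanges::coverage(IRanges::IRanges(sub$start + 1L, sub$end),
                      width = as.integer(genome_lengths[[ch]]))
  })
  names(cov) <- chroms

  # distinct coverage levels with base counts across the whole genome
  vals <- unlist(lapply(cov, S4Vectors::runValue), use.names = FALSE)
  lens <- unlist(lapply(cov, S4Vectors::runLength), use.names = FALSE)
  count_by_val <- tapply(as.numeric(lens), vals, sum)
  levels <- as.integer(names(count_by_val))
  p <- stats::ppois(levels - 1L, lambda, lower.tail = FALSE)
  adj <- bh_adjust_weighted(p, as.numeric(count_by_val))
  sig_levels <- levels[adj < q_cutoff]
  if (length(sig_levels) == 0) return(empty_peaks())
  vmin <- min(sig_levels)

  out <- list()
  for (ch in chroms) {
    sig <- IRanges::slice(cov[[ch]], lower = vmin, rangesOnly = TRUE)
    if (length(sig) == 0) next
    runs <- data.frame(chrom = ch, start = IRanges::start(sig) - 1L,
                       end = IRanges::end(sig))
    runs <- merge_intervals(runs, max_gap = max_gap)
    runs <- runs[runs$end - runs$start >= min_width, , drop = FALSE]
    if (nrow(runs) == 0) next
    v <- as.integer(cov[[ch]])
    runs$height <- NA_real_
    runs$summit_offset <- NA_integer_
    for (i in seq_len(nrow(runs))) {
      seg <- v[(runs$start[i] + 1L):runs$end[i]]
      runs$height[i] <- max(seg)
      runs$summit_offset[i] <- which.max(seg) - 1L  # leftmost argmax
    }
    out[[ch]] <- runs
  }
  if (length(out) == 0) return(empty_peaks())
  res <- sort_intervals(do.call(rbind, out))
  res <- as_peaks(res)
  res$name <- sprintf("pileup_%d", seq_len(nrow(res)))
  res$score <- pmin(1000, round(res$height))
  res
}
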