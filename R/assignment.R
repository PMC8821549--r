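#' Build peak-to-gene assignment windows
#'
#' Each gene's assignment window is its gene-body interval (introns
#' included) extended by `flank` bases on both sides, irrespective of
#' strand, clipped at 0 and — when chromosome sizes are supplied — at the
#' chromosome end.  The default 5 kb flank matches the convention of
#' assigning a peak to a gene when it falls on the gene body or within
#' 5 kb upstream or downstream.
#'
#' @param genes gene-model data frame (see [read_gff3_genes()]).
#' @param flank non-negative integer extension (bases).
#' @param chrom_sizes optional named vector of chromosome lengths; every
#'   gene chromosome must then be present.
#' @return Data frame `gene_id`, `chrom`, `start`, `end` (the windows),
#'   with the flank stored as attribute `"flank"`.
#' @export
build_windows <- function(genes, flank = 5000L, chrom_sizes = NULL) {
  if (length(flank) != 1L || is.na(flank) || flank < 0)
    stop("flank must be a single non-negative integer", call. = FALSE)
  validate_intervals(genes, "gene")
  if (!"gene_id" %in% names(genes))
    stop("genes must carry a gene_id column", call. = FALSE)
  start <- pmax(0L, genes$start - as.integer(flank))
  end <- genes$end + as.integer(flank)
  if (!is.null(chrom_sizes)) {
    unknown <- setdiff(unique(genes$chrom), names(chrom_sizes))
    if (length(unknown))
      stop("gene chromosome(s) missing from chrom_sizes: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    end <- pmin(end, as.integer(chrom_sizes[genes$chrom]))
  }
  out <- data.frame(gene_id = genes$gene_id, chrom = genes$chrom,
                    start = start, end = end, stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$start, out$end, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "flank") <- as.integer(flank)
  out
}

#' Assign consensus peaks to genes through assignment windows
#'
#' A peak is assigned to every gene whose window it overlaps by at least
#' one base ("and/or" semantics — a peak spanning several windows counts
#' for all of them; no nearest-gene tie-breaking).  Peaks overlapping no
#' window are categorised `not_annotated`.
#'
#' @param peaks `consensus_peaks` object or interval data frame (an id
#'   column `consensus_id` is created if missing).
#' @param windows window data frame from [build_windows()].
#' @return Data frame `consensus_peak_id`, `gene_ids` (list column of
#'   character vectors, sorted), `category`
#'   (`"genic_or_flank"`/`"not_annotated"`), in peak order.
#' @export
assign_peaks <- function(peaks, windows) {
  x <- peak_frame(peaks)
  validate_intervals(windows, "window")
  gene_ids <- rep(list(character()), nrow(x))
  if (nrow(x) && nrow(windows)) {
    seqlev <- sort(unique(c(x$chrom, windows$chrom)))
    hit <- GenomicRanges::findOverlaps(gi_to_gr(x, seqlev),
                                       gi_to_gr(windows, seqlev))
    qi <- S4Vectors::queryHits(hit)
    si <- S4Vectors::subjectHits(hit)
    if (length(qi)) {
      by_peak <- split(windows$gene_id[si], qi)
      for (k in names(by_peak))
        gene_ids[[as.integer(k)]] <- sort(unique(by_peak[[k]]))
    }
  }
  out <- data.frame(consensus_peak_id = x$consensus_id,
                    stringsAsFactors = FALSE)
  out$gene_ids <- gene_ids
  out$category <- ifelse(lengths(gene_ids) > 0, "genic_or_flank",
                         "not_annotated")
  out
}

#' TR-bound gene set from peak assignments
#'
#' The union of gene ids over all peak assignments: a gene is bound iff
#' at least one consensus peak overlaps its assignment window.
#'
#' @param assignments data frame from [assign_peaks()].
#' @return Sorted character vector of gene ids.
#' @export
bound_gene_set <- function(assignments) {
  sort(unique(unlist(assignments$gene_ids, use.names = FALSE)))
}

#' Classify peak locations relative to genes
#'
#' Labels each peak `gene_body` (overlaps a gene body by >= 1 base;
#' takes precedence), `flank_only` (overlaps a flank-extended window but
#' no body) or `intergenic`.
#'
#' @param peaks `consensus_peaks` object or interval data frame.
#' @param genes gene-model data frame.
#' @param flank flank used for the windows (bases).
#' @return List with `labels` (data frame `consensus_peak_id`, `label`)
#'   and `counts` (named integer vector over the three categories).
#' @export
classify_peak_locations <- function(peaks, genes, flank = 5000L) {
  x <- peak_frame(peaks)
  validate_intervals(genes, "gene")
  label <- rep("intergenic", nrow(x))
  if (nrow(x) && nrow(genes)) {
    seqlev <- sort(unique(c(x$chrom, genes$chrom)))
    gr <- gi_to_gr(x, seqlev)
    body_hit <- S4Vectors::queryHits(
      GenomicRanges::findOverlaps(gr, gi_to_gr(genes, seqlev)))
    win <- build_windows(genes, flank = flank)
    win_hit <- S4Vectors::queryHits(
      GenomicRanges::findOverlaps(gr, gi_to_gr(win, seqlev)))
    label[unique(win_hit)] <- "flank_only"
    label[unique(body_hit)] <- "gene_body"
  }
  counts <- c(gene_body = sum(label == "gene_body"),
              flank_only = sum(label == "flank_only"),
              intergenic = sum(label == "intergenic"))
  list(labels = data.frame(consensus_peak_id = x$consensus_id,
                           label = label, stringsAsFactors = FALSE),
       counts = counts)
}

#' Write peak-to-gene assignments as TSV
#'
#' Gene ids are semicolon-joined; empty assignments are written as an
#' empty field.
#'
#' @param assignments data frame from [assign_peaks()].
#' @param peaks the peaks the assignments were computed from (for
#'   coordinates).
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_assignments <- function(assignments, peaks, path) {
  x <- peak_frame(peaks)
  m <- match(assignments$consensus_peak_id, x$consensus_id)
  out <- data.frame(
    consensus_peak_id = assignments$consensus_peak_id,
    chrom = x$chrom[m], start = x$start[m], end = x$end[m],
    gene_ids = vapply(assignments$gene_ids, paste, character(1),
                      collapse = ";"),
    category = assignments$category, stringsAsFactors = FALSE)
  write_tsv(out, path)
}
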