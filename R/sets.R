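#' Labelled gene sets
#'
#' A light wrapper pairing a label with a deduplicated, sorted vector of
#' gene identifiers.  All set-analytics functions also accept plain
#' character vectors.
#'
#' @param label set label.
#' @param gene_ids character vector of gene ids (duplicates dropped).
#' @return Object of class `gene_set`.
#' @export
gene_set <- function(label, gene_ids) {
  structure(list(label = as.character(label),
                 gene_ids = sort(unique(as.character(gene_ids)))),
            class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat("Gene set '", x$label, "': ", length(x$gene_ids), " genes\n",
      sep = "")
  invisible(x)
}

set_ids <- function(x) {
  if (inherits(x, "gene_set")) x$gene_ids else unique(as.character(x))
}
set_label <- function(x, default) {
  if (inherits(x, "gene_set")) x$label else default
}

#' Select T3-regulated genes from an expression table
#'
#' Applies the regulation cutoff used for the RNA-Seq comparison: a gene
#' is called regulated when its fold change reaches `fold_cutoff`
#' (inclusive, applied on the log2 scale) and its FDR is strictly below
#' `fdr_cutoff`.  Records missing either value for the chosen genotype
#' are excluded.
#'
#' @param records expression data frame (see [read_expression_table()]).
#' @param genotype `"wt"` or `"ko"`.
#' @param direction `"up"` (log2fc >= log2(fold_cutoff)) or `"down"`
#'   (log2fc <= -log2(fold_cutoff)).
#' @param fold_cutoff linear fold-change cutoff (> 1; default 1.5).
#' @param fdr_cutoff FDR cutoff (strict `<`; default 0.05).
#' @return A [gene_set()] labelled `<genotype>_<direction>`.
#' @export
select_regulated <- function(records, genotype = c("wt", "ko"),
                             direction = c("up", "down"),
                             fold_cutoff = 1.5, fdr_cutoff = 0.05) {
  genotype <- match.arg(genotype)
  direction <- match.arg(direction)
  if (fold_cutoff <= 1)
    stop("fold_cutoff must be > 1", call. = FALSE)
  if (fdr_cutoff <= 0 || fdr_cutoff > 1)
    stop("fdr_cutoff must be in (0, 1]", call. = FALSE)
  lfc <- records[[paste0("log2fc_", genotype)]]
  fdr <- records[[paste0("fdr_", genotype)]]
  if (is.null(lfc) || is.null(fdr))
    stop("records lack log2fc_/fdr_ columns for genotype ", genotype,
         call. = FALSE)
  thr <- log2(fold_cutoff)
  ok <- !is.na(lfc) & !is.na(fdr) & fdr < fdr_cutoff &
    (if (direction == "up") lfc >= thr else lfc <= -thr)
  gene_set(paste(genotype, direction, sep = "_"), records$gene_id[ok])
}

#' Venn region cardinalities for 2 or 3 gene sets
#'
#' Computes exact region cardinalities by set algebra, the union size by
#' inclusion-exclusion, and pairwise overlap percentages (each rounded to
#' the nearest integer, half away from zero) in the style of
#' "x% of set A were in set B".
#'
#' @param sets list of 2 or 3 [gene_set()]s or character vectors;
#'   list names override set labels.
#' @return Object of class `venn_result`: list with `labels`, `regions`
#'   (named integer vector; 3 regions for 2 sets, 7 for 3), `union_size`,
#'   `set_sizes`, and `percentages`.
#' @examples
#' venn(list(A = c("g1", "g2"), B = c("g2", "g3")))
#' @export
venn <- function(sets) {
  if (!is.list(sets) || length(sets) < 2L)
    stop("need at least 2 gene sets", call. = FALSE)
  if (length(sets) > 3L)
    stop("more than 3 sets are unsupported", call. = FALSE)
  labels <- names(sets)
  if (is.null(labels)) labels <- rep("", length(sets))
  labels <- mapply(function(s, l, i) {
    if (nzchar(l)) l else set_label(s, paste0("set", i))
  }, sets, labels, seq_along(sets))
  ids <- lapply(sets, set_ids)
  names(ids) <- labels
  if (length(ids) == 2L) {
    a <- ids[[1]]; b <- ids[[2]]
    regions <- c(length(setdiff(a, b)), length(setdiff(b, a)),
                 length(intersect(a, b)))
    names(regions) <- c(paste0("only_", labels[1]),
                        paste0("only_", labels[2]),
                        paste(labels[1], labels[2], sep = "_and_"))
  } else {
    a <- ids[[1]]; b <- ids[[2]]; cc <- ids[[3]]
    abc <- intersect(intersect(a, b), cc)
    regions <- c(length(setdiff(setdiff(a, b), cc)),
                 length(setdiff(setdiff(b, a), cc)),
                 length(setdiff(setdiff(cc, a), b)),
                 length(setdiff(intersect(a, b), cc)),
                 length(setdiff(intersect(a, cc), b)),
                 length(setdiff(intersect(b, cc), a)),
                 length(abc))
    names(regions) <- c(paste0("only_", labels),
                        paste(labels[1], labels[2], sep = "_and_"),
                        paste(labels[1], labels[3], sep = "_and_"),
                        paste(labels[2], labels[3], sep = "_and_"),
                        paste(labels, collapse = "_and_"))
  }
  union_size <- length(unique(unlist(ids, use.names = FALSE)))
  stopifnot(sum(regions) == union_size)
  pct <- list()
  for (i in seq_along(ids)) for (j in seq_along(ids)) {
    if (i == j || length(ids[[i]]) == 0) next
    pct[[paste0("pct_", labels[i], "_in_", labels[j])]] <-
      overlap_percent(length(intersect(ids[[i]], ids[[j]])),
                      length(ids[[i]]))
  }
  structure(list(labels = unname(labels), regions = regions,
                 union_size = union_size,
                 set_sizes = stats::setNames(lengths(ids), labels),
                 percentages = pct),
            class = "venn_result")
}

#' @export
print.venn_result <- function(x, ...) {
  cat("Venn of", paste(x$labels, collapse = ", "), "- union",
      x$union_size, "\n")
  print(x$regions)
  invisible(x)
}

#' Integer overlap percentage
#'
#' `round(100 * part / whole)` with halves rounded away from zero,
#' matching the integer-percent style of published overlap figures
#' (e.g. 896/4605 -> 19).
#'
#' @param part overlap cardinality (`0 <= part <= whole`).
#' @param whole reference cardinality (> 0).
#' @return Integer percent.
#' @export
overlap_percent <- function(part, whole) {
  if (length(whole) != 1L || is.na(whole) || whole <= 0)
    stop("whole must be a single positive count", call. = FALSE)
  if (length(part) != 1L || is.na(part) || part < 0 || part > whole)
    stop("part must satisfy 0 <= part <= whole", call. = FALSE)
  as.integer(round_half_up(100 * part / whole))
}

#' Partition bound genes by genotype
#'
#' Splits TR-bound genes into those bound only in wild type, bound in
#' both genotypes, and bound only in the knockout.
#'
#' @param wt_bound,ko_bound [gene_set()]s or character vectors.
#' @return List of three [gene_set()]s `wt_only`, `common`, `ko_only`
#'   (class `genotype_partition`).
#' @export
partition_by_genotype <- function(wt_bound, ko_bound) {
  wt <- set_ids(wt_bound)
  ko <- set_ids(ko_bound)
  structure(list(wt_only = gene_set("wt_only", setdiff(wt, ko)),
                 common = gene_set("common", intersect(wt, ko)),
                 ko_only = gene_set("ko_only", setdiff(ko, wt))),
            class = "genotype_partition")
}

#' Fold-change matrix over a genotype partition
#'
#' One row per partitioned gene with its wild-type and knockout log2 fold
#' changes; genes absent from the expression table get `NA` values.
#' Blocks are ordered `wt_only`, `common`, `ko_only`; within a block rows
#' are ordered by `log2fc_wt` descending with `NA` last — the layout of a
#' genotype-comparison heat map.
#'
#' @param partition result of [partition_by_genotype()].
#' @param records expression data frame.
#' @return Data frame `gene_id`, `block`, `log2fc_wt`, `log2fc_ko`
#'   (class `fold_change_matrix`).
#' @export
fold_change_matrix <- function(partition, records) {
  blocks <- c("wt_only", "common", "ko_only")
  rows <- lapply(blocks, function(b) {
    g <- set_ids(partition[[b]])
    if (length(g) == 0) return(NULL)
    m <- match(g, records$gene_id)
    out <- data.frame(gene_id = g, block = b,
                      log2fc_wt = records$log2fc_wt[m],
                      log2fc_ko = records$log2fc_ko[m],
                      stringsAsFactors = FALSE)
    out[order(-out$log2fc_wt, out$gene_id, na.last = TRUE), , drop = FALSE]
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(gene_id = character(), block = character(),
                      log2fc_wt = numeric(), log2fc_ko = numeric(),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("fold_change_matrix", "data.frame")
  out
}

#' Heat map of a fold-change matrix
#'
#' Convenience renderer (requires the pheatmap package); rows follow the
#' matrix ordering, colours span the log2 fold-change range.
#'
#' @param fcm result of [fold_change_matrix()].
#' @param ... passed to [pheatmap::pheatmap()].
#' @return The pheatmap object, invisibly.
#' @export
fold_change_heatmap <- function(fcm, ...) {
  if (!requireNamespace("pheatmap", quietly = TRUE))
    stop("fold_change_heatmap requires the pheatmap package",
         call. = FALSE)
  m <- as.matrix(fcm[, c("log2fc_wt", "log2fc_ko")])
  rownames(m) <- fcm$gene_id
  invisible(pheatmap::pheatmap(m, cluster_rows = FALSE,
                               cluster_cols = FALSE, ...))
}

#' Write a gene set as one-id-per-line text
#'
#' @param x [gene_set()] or character vector.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_gene_set <- function(x, path) {
  writeLines(set_ids(x), path)
  invisible(path)
}
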