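#' Read gene models from a GFF3 file
#'
#' Extracts records of one feature type (by default `gene`) and converts
#' the GFF3 1-based inclusive coordinates to the package's 0-based
#' half-open convention (`start - 1`, `end`).  The stable identifier is
#' taken from the `ID` attribute and the display symbol from `Name` when
#' present.  The gene interval is the full gene-body span, introns
#' included, as annotated on the `gene` feature line.
#'
#' @param path GFF3 file path.
#' @param feature feature type (column 3) to keep.
#' @return Data frame with columns `gene_id`, `name`, `chrom`, `start`,
#'   `end`, `strand`.
#' @export
read_gff3_genes <- function(path, feature = "gene") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0) return(empty_genes())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf != 9L)
  if (length(bad))
    stop("malformed GFF3 line ", lineno[bad[1]], " in ", path,
         ": expected 9 tab-separated columns, found ", nf[bad[1]],
         call. = FALSE)
  type <- vapply(fields, `[[`, character(1), 3L)
  sel <- which(type == feature)
  if (length(sel) == 0) return(empty_genes())
  fields <- fields[sel]
  lineno <- lineno[sel]
  chrom <- vapply(fields, `[[`, character(1), 1L)
  start1 <- suppressWarnings(as.integer(vapply(fields, `[[`, character(1), 4L)))
  end1 <- suppressWarnings(as.integer(vapply(fields, `[[`, character(1), 5L)))
  bad <- which(is.na(start1) | is.na(end1) | start1 < 1L | start1 > end1)
  if (length(bad))
    stop("malformed GFF3 line ", lineno[bad[1]], " in ", path,
         ": invalid coordinates", call. = FALSE)
  strand <- vapply(fields, `[[`, character(1), 7L)
  attrs <- vapply(fields, `[[`, character(1), 9L)
  attr_value <- function(s, key) {
    parts <- strsplit(s, ";", fixed = TRUE)[[1]]
    kv <- strsplit(trimws(parts), "=", fixed = TRUE)
    for (p in kv) if (length(p) == 2L && p[1] == key) return(p[2])
    NA_character_
  }
  gene_id <- vapply(attrs, attr_value, character(1), key = "ID",
                    USE.NAMES = FALSE)
  bad <- which(is.na(gene_id))
  if (length(bad))
    stop("GFF3 line ", lineno[bad[1]], " in ", path,
         ": '", feature, "' record missing ID attribute", call. = FALSE)
  dup <- gene_id[duplicated(gene_id)]
  if (length(dup))
    stop("duplicate gene_id in ", path, ": ",
         paste(unique(utils::head(dup, 5L)), collapse = ", "),
         call. = FALSE)
  name <- vapply(attrs, attr_value, character(1), key = "Name",
                 USE.NAMES = FALSE)
  x <- data.frame(gene_id = gene_id, name = name, chrom = chrom,
                  start = start1 - 1L, end = end1, strand = strand,
                  stringsAsFactors = FALSE)
  validate_intervals(x, "gene")
  sort_intervals(x)
}

empty_genes <- function() {
  data.frame(gene_id = character(), name = character(), chrom = character(),
             start = integer(), end = integer(), strand = character(),
             stringsAsFactors = FALSE)
}

#' Write gene models as GFF3
#'
#' Inverse of [read_gff3_genes()]: internal 0-based half-open coordinates
#' are converted back to 1-based inclusive on output.
#'
#' @param genes gene-model data frame.
#' @param path output path.
#' @param feature feature type written in column 3.
#' @param source value for column 2.
#' @return Invisibly, `path`.
#' @export
write_gff3 <- function(genes, path, feature = "gene", source = "trbound") {
  validate_intervals(genes, "gene")
  genes <- sort_intervals(genes)
  attrs <- ifelse(is.na(genes$name) | !nzchar(genes$name),
                  paste0("ID=", genes$gene_id),
                  paste0("ID=", genes$gene_id, ";Name=", genes$name))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (nrow(genes))
    writeLines(paste(genes$chrom, source, feature, genes$start + 1L,
                     genes$end, ".", genes$strand, ".", attrs, sep = "\t"),
               con)
  invisible(path)
}

#' Read a FASTA file into a named character vector
#'
#' Sequences are uppercased on read.  Duplicate headers are an error.
#'
#' @param path FASTA file path.
#' @return Named character vector mapping sequence name to sequence.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  info <- file.info(path)
  if (!is.na(info$size) && info$size == 0) return(stats::setNames(character(), character()))
  set <- Biostrings::readDNAStringSet(path)
  nm <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(nm))
    stop("duplicate FASTA header in ", path, ": ",
         nm[duplicated(nm)][1], call. = FALSE)
  stats::setNames(toupper(as.character(set)), nm)
}

#' Write a named character vector of sequences as FASTA
#'
#' @param seqs named character vector (names become headers).
#' @param path output path.
#' @param width line wrap width.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  if (length(seqs) && (is.null(names(seqs)) || anyDuplicated(names(seqs))))
    stop("sequences must have unique names", call. = FALSE)
  set <- Biostrings::DNAStringSet(toupper(seqs))
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read a differential-expression table
#'
#' Expects a TSV with a header row.  Column names are configurable; blank
#' cells become `NA`.  FDR values outside \[0,1\] and duplicate gene ids
#' are errors.
#'
#' @param path TSV path.
#' @param gene_col,log2fc_wt_col,fdr_wt_col,log2fc_ko_col,fdr_ko_col
#'   column names in the file header.
#' @return Data frame with columns `gene_id`, `log2fc_wt`, `fdr_wt`,
#'   `log2fc_ko`, `fdr_ko`.
#' @export
read_expression_table <- function(path, gene_col = "gene_id",
                                  log2fc_wt_col = "log2fc_wt",
                                  fdr_wt_col = "fdr_wt",
                                  log2fc_ko_col = "log2fc_ko",
                                  fdr_ko_col = "fdr_ko") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE,
                           na.strings = c("", "NA"))
  need <- c(gene_col, log2fc_wt_col, fdr_wt_col, log2fc_ko_col, fdr_ko_col)
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols))
    stop("expression table ", path, " lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  x <- data.frame(gene_id = as.character(tab[[gene_col]]),
                  log2fc_wt = as.numeric(tab[[log2fc_wt_col]]),
                  fdr_wt = as.numeric(tab[[fdr_wt_col]]),
                  log2fc_ko = as.numeric(tab[[log2fc_ko_col]]),
                  fdr_ko = as.numeric(tab[[fdr_ko_col]]),
                  stringsAsFactors = FALSE)
  dup <- x$gene_id[duplicated(x$gene_id)]
  if (length(dup))
    stop("duplicate gene_id in ", path, ": ", dup[1], call. = FALSE)
  for (col in c("fdr_wt", "fdr_ko")) {
    v <- x[[col]]
    bad <- which(!is.na(v) & (v < 0 | v > 1))
    if (length(bad))
      stop("FDR value outside [0,1] in ", path, " (", col, " = ",
           v[bad[1]], ", gene ", x$gene_id[bad[1]], ")", call. = FALSE)
  }
  x
}

#' Write a data frame as a TSV with header
#'
#' @param x data frame.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read gene-set annotations in GMT format
#'
#' Each line is `term_id TAB description TAB gene1 TAB gene2 ...`.  Genes
#' are deduplicated within a term; a line with fewer than 3 fields (no
#' genes) is an error.
#'
#' @param path GMT file path.
#' @return List of term annotations, each a list with `term_id`,
#'   `term_name` and `gene_ids` (character vector, unique).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  keep <- nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  out <- vector("list", length(fields))
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    if (length(f) < 3L)
      stop("malformed GMT line ", lineno[i], " in ", path,
           ": expected term_id, description and at least one gene",
           call. = FALSE)
    genes <- unique(f[-(1:2)])
    genes <- genes[nzchar(genes)]
    if (length(genes) == 0)
      stop("malformed GMT line ", lineno[i], " in ", path,
           ": term has no genes", call. = FALSE)
    out[[i]] <- list(term_id = f[1], term_name = f[2], gene_ids = genes)
  }
  out
}

#' Write gene-set annotations in GMT format
#'
#' @param terms list of term annotations (as from [read_gmt()]).
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_gmt <- function(terms, path) {
  lines <- vapply(terms, function(t) {
    paste(c(t$term_id, t$term_name, t$gene_ids), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
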