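#' Run the full TR target-gene analysis
#'
#' Orchestrates the stages in order — replicate-consensus peak
#' determination per sample, peak-to-gene assignment, DR4 scanning
#' (when a genome is supplied), bound-gene set analytics against the
#' expression table, term enrichment and genotype-differential
#' enrichment (when a GMT is supplied) — writing per-stage outputs under
#' `out_dir` and a machine-readable `report.json`.  All inputs are
#' checked before any stage runs; a missing file aborts with no partial
#' outputs.
#'
#' @param peak_files named list: sample id -> character vector of
#'   per-replicate narrowPeak paths.  Samples named `WT_minusT3`,
#'   `WT_plusT3`, `KO_minusT3`, `KO_plusT3` enable the genotype and
#'   treatment comparisons.
#' @param gff3 gene annotation path.
#' @param out_dir output directory (created).
#' @param fasta optional genome FASTA for DR4 counting.
#' @param expression optional expression TSV (see
#'   [read_expression_table()]).
#' @param gmt optional GMT path for enrichment.
#' @param flank assignment-window flank (bases).
#' @param fold_cutoff,fdr_cutoff regulation cutoffs for
#'   [select_regulated()].
#' @param enrich_fdr FDR threshold for [enrich()].
#' @param min_width minimum consensus width.
#' @param quiet suppress progress messages.
#' @return The run report (class `tr_run_report`), invisibly: a list
#'   with per-sample consensus counts, bound-gene set sizes, Venn
#'   regions and percentages, TRE totals, enrichment summaries, the
#'   differential term list, and the configuration echo.
#' @export
run_tr_pipeline <- function(peak_files, gff3, out_dir, fasta = NULL,
                            expression = NULL, gmt = NULL, flank = 5000L,
                            fold_cutoff = 1.5, fdr_cutoff = 0.05,
                            enrich_fdr = 0.05, min_width = 1L,
                            quiet = FALSE) {
  say <- function(...) if (!quiet) message("[trbound] ", ...)

  # pre-flight: every referenced input must exist before any stage runs
  inputs <- c(unlist(peak_files, use.names = FALSE), gff3, fasta,
              expression, gmt)
  missing_in <- inputs[!file.exists(inputs)]
  if (length(missing_in))
    stop("missing input file(s): ", paste(missing_in, collapse = ", "),
         call. = FALSE)
  if (is.null(names(peak_files)) || any(!nzchar(names(peak_files))))
    stop("peak_files must be a named list (sample id -> replicate files)",
         call. = FALSE)

  dir.create(file.path(out_dir, "consensus"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(out_dir, "genes"), showWarnings = FALSE)

  genes <- read_gff3_genes(gff3)
  windows <- build_windows(genes, flank = flank)
  say("annotation: ", nrow(genes), " genes (flank ", flank, " bp)")

  report <- list(flank = flank, fold_cutoff = fold_cutoff,
                 fdr_cutoff = fdr_cutoff, enrich_fdr = enrich_fdr,
                 version = as.character(utils::packageVersion("trbound")),
                 samples = list())
  consensus <- list()
  bound <- list()
  for (sample_id in names(peak_files)) {
    reps <- lapply(peak_files[[sample_id]], read_peaks,
                   sample_id = sample_id)
    names(reps) <- sprintf("rep%d", seq_along(reps))
    cp <- intersect_replicates(reps, min_width = min_width,
                               sample_id = sample_id)
    consensus[[sample_id]] <- cp
    asn <- assign_peaks(cp, windows)
    bg <- bound_gene_set(asn)
    bound[[sample_id]] <- bg
    loc <- classify_peak_locations(cp, genes, flank = flank)

    out_peaks <- cp$peaks
    out_bed <- data.frame(chrom = out_peaks$chrom,
                          start = out_peaks$start, end = out_peaks$end,
                          name = out_peaks$consensus_id,
                          score = round(pmin(1000, out_peaks$height * 10)),
                          strand = ".", stringsAsFactors = FALSE)
    write_bed(out_bed, file.path(out_dir, "consensus",
                                 paste0(sample_id, ".bed")))
    write_tsv(cp$support, file.path(out_dir, "consensus",
                                    paste0(sample_id, "_support.tsv")))
    write_assignments(asn, cp, file.path(out_dir, "consensus",
                                         paste0(sample_id,
                                                "_assignment.tsv")))
    write_gene_set(bg, file.path(out_dir, "genes",
                                 paste0(sample_id, "_bound.txt")))
    say(sample_id, ": ", length(reps), " replicates -> ",
        nrow(cp$peaks), " consensus peaks, ", length(bg),
        " bound genes")
    report$samples[[sample_id]] <-
      list(n_replicates = length(reps),
           n_consensus_peaks = nrow(cp$peaks),
           n_bound_genes = length(bg),
           location_counts = as.list(loc$counts))
  }

  if (!is.null(fasta)) {
    genome <- read_fasta(fasta)
    tre_total <- 0L
    for (sample_id in names(consensus)) {
      tres <- count_tres_in_peaks(consensus[[sample_id]], genome)
      write_tsv(tres$counts,
                file.path(out_dir, "consensus",
                          paste0(sample_id, "_tre_counts.tsv")))
      report$samples[[sample_id]]$n_tres <- tres$total
      tre_total <- tre_total + tres$total
    }
    report$tre_total <- tre_total
    say("DR4 scan: ", tre_total, " elements in consensus peaks")
  }

  have <- function(s) s %in% names(bound)
  if (have("WT_minusT3") && have("WT_plusT3")) {
    wt_all <- gene_set("WT_bound",
                       union(bound$WT_minusT3, bound$WT_plusT3))
    v_wt <- venn(list(WT_minusT3 = bound$WT_minusT3,
                      WT_plusT3 = bound$WT_plusT3))
    report$venn_wt_treatment <- list(regions = as.list(v_wt$regions),
                                     union = v_wt$union_size,
                                     percentages = v_wt$percentages)
    say("WT -T3/+T3 union: ", v_wt$union_size, " bound genes")
  } else if (length(bound)) {
    wt_all <- gene_set("WT_bound", unlist(bound[grep("^WT", names(bound))],
                                          use.names = FALSE))
  } else wt_all <- gene_set("WT_bound", character())

  ko_all <- NULL
  if (have("KO_minusT3") && have("KO_plusT3")) {
    ko_all <- gene_set("KO_bound",
                       union(bound$KO_minusT3, bound$KO_plusT3))
    v_ko <- venn(list(KO_minusT3 = bound$KO_minusT3,
                      KO_plusT3 = bound$KO_plusT3))
    report$venn_ko_treatment <- list(regions = as.list(v_ko$regions),
                                     union = v_ko$union_size,
                                     percentages = v_ko$percentages)
  }

  partition <- NULL
  if (!is.null(ko_all)) {
    partition <- partition_by_genotype(wt_all, ko_all)
    report$genotype_partition <-
      list(wt_only = length(partition$wt_only$gene_ids),
           common = length(partition$common$gene_ids),
           ko_only = length(partition$ko_only$gene_ids))
    for (b in c("wt_only", "common", "ko_only"))
      write_gene_set(partition[[b]],
                     file.path(out_dir, "genes", paste0(b, ".txt")))
  }

  records <- NULL
  if (!is.null(expression)) {
    records <- read_expression_table(expression)
    up_wt <- select_regulated(records, "wt", "up", fold_cutoff,
                              fdr_cutoff)
    down_wt <- select_regulated(records, "wt", "down", fold_cutoff,
                                fdr_cutoff)
    write_gene_set(up_wt, file.path(out_dir, "genes", "wt_up.txt"))
    write_gene_set(down_wt, file.path(out_dir, "genes", "wt_down.txt"))
    nb <- length(wt_all$gene_ids)
    if (nb > 0) {
      ov_up <- length(intersect(wt_all$gene_ids, up_wt$gene_ids))
      ov_down <- length(intersect(wt_all$gene_ids, down_wt$gene_ids))
      report$regulation <- list(
        n_bound = nb, n_up = length(up_wt$gene_ids),
        n_down = length(down_wt$gene_ids),
        n_bound_up = ov_up, n_bound_down = ov_down,
        pct_bound_up = overlap_percent(ov_up, nb),
        pct_bound_down = overlap_percent(ov_down, nb))
      say("bound genes T3-upregulated: ",
          report$regulation$pct_bound_up, "%")
    }
    if (!is.null(partition)) {
      fcm <- fold_change_matrix(partition, records)
      write_tsv(fcm, file.path(out_dir, "genes",
                               "fold_change_matrix.tsv"))
    }
  }

  if (!is.null(gmt)) {
    terms <- read_gmt(gmt)
    background <- gene_set("annotation", genes$gene_id)
    enr_wt <- enrich(gene_set("wt", intersect(wt_all$gene_ids,
                                              background$gene_ids)),
                     background, terms, fdr_threshold = enrich_fdr)
    write_tsv(as.data.frame(enr_wt),
              file.path(out_dir, "enrichment_wt.tsv"))
    report$enrichment <- list(n_terms = nrow(enr_wt),
                              n_enriched_wt = sum(enr_wt$enriched))
    if (!is.null(ko_all)) {
      enr_ko <- enrich(gene_set("ko", intersect(ko_all$gene_ids,
                                                background$gene_ids)),
                       background, terms, fdr_threshold = enrich_fdr)
      write_tsv(as.data.frame(enr_ko),
                file.path(out_dir, "enrichment_ko.tsv"))
      diff <- differential_enrichment(enr_wt, enr_ko)
      report$enrichment$n_enriched_ko <- sum(enr_ko$enriched)
      report$enrichment$differential_terms <- diff$term_id
      jsonlite::write_json(diff$term_id,
                           file.path(out_dir,
                                     "differential_terms.json"))
      say("differential enrichment: ", nrow(diff),
          " wild-type-specific terms")
    }
  }

  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  class(report) <- "tr_run_report"
  invisible(report)
}

#' @export
print.tr_run_report <- function(x, ...) {
  cat("TR target-gene pipeline report\n")
  for (s in names(x$samples))
    cat(sprintf("  %-12s %5d consensus peaks, %5d bound genes\n", s,
                x$samples[[s]]$n_consensus_peaks,
                x$samples[[s]]$n_bound_genes))
  if (!is.null(x$venn_wt_treatment))
    cat("  WT union:", x$venn_wt_treatment$union, "bound genes\n")
  if (!is.null(x$genotype_partition))
    cat("  genotype partition: wt_only", x$genotype_partition$wt_only,
        "| common", x$genotype_partition$common, "| ko_only",
        x$genotype_partition$ko_only, "\n")
  if (!is.null(x$regulation))
    cat("  ", x$regulation$pct_bound_up,
        "% of bound genes T3-upregulated\n", sep = "")
  invisible(x)
}
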