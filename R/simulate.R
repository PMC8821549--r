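#' Simulation configuration
#'
#' Parameters of the synthetic ChIP-Seq experiment: a toy genome with
#' non-overlapping gene models whose assignment windows are kept disjoint
#' (so every planted genic site maps to exactly one gene), planted TR
#' binding sites each carrying one embedded DR4 element, three technical
#' replicates per sample across two genotypes (wild type, TRalpha
#' knockout) and two treatments (-T3, +T3), peak-call noise (boundary
#' jitter, per-replicate dropouts and false peaks), knockout-attenuated
#' binding, and an expression table statistically linked to binding.
#'
#' Defaults encode the emulated study design: 3 technical replicates;
#' 60% of true sites inside gene windows (most peaks intergenic);
#' knockout retention 0.7 (about 70% of wild-type-bound genes remain
#' bound via TRbeta); `t3_gain = 0.3` (the +T3 detectable set is about
#' 1.3x the -T3 set); 19% of bound genes T3-upregulated in wild type.
#'
#' @param seed integer RNG seed (all randomness derives from it).
#' @param n_chroms,chrom_length toy genome shape (bases per chromosome).
#' @param n_genes,gene_length gene count and length range (bases).
#' @param flank assignment-window flank (bases).
#' @param n_true_sites number of planted binding sites.
#' @param fraction_sites_in_windows fraction of sites placed inside gene
#'   windows; the remainder are intergenic.
#' @param site_width site width range (bases).
#' @param jitter_sd Gaussian boundary jitter SD per replicate (bases).
#' @param fp_rate false peaks per replicate, as a fraction of the
#'   sample's detectable true-site count (Poisson mean).
#' @param dropout_rate per-replicate per-site dropout probability.
#' @param n_replicates technical replicates per sample.
#' @param ko_retention probability a true site remains detectable in the
#'   knockout.
#' @param t3_gain fractional increase of the +T3-detectable site count
#'   over the -T3 (constitutive) count.
#' @param p_up_given_bound probability a wild-type-bound gene is
#'   T3-upregulated.
#' @param effect_mean,effect_sd log2 fold-change distribution of
#'   upregulated genes.
#' @param ko_attenuation multiplier applied to the wild-type effect for
#'   knockout-retained genes.
#' @param min_gene_gap minimum uncovered bases between adjacent
#'   assignment windows.
#' @param site_margin clearance kept between planted sites and window
#'   boundaries / other sites (bases).
#' @return Object of class `sim_config` (a validated list).
#' @export
sim_config <- function(seed = 1L, n_chroms = 2L, chrom_length = 1500000L,
                       n_genes = 200L, gene_length = c(500L, 3000L),
                       flank = 5000L, n_true_sites = 250L,
                       fraction_sites_in_windows = 0.6,
                       site_width = c(150L, 400L), jitter_sd = 25,
                       fp_rate = 0.1, dropout_rate = 0.05,
                       n_replicates = 3L, ko_retention = 0.7,
                       t3_gain = 0.3, p_up_given_bound = 0.19,
                       effect_mean = 2, effect_sd = 0.5,
                       ko_attenuation = 0.5, min_gene_gap = 200L,
                       site_margin = 200L) {
  cfg <- list(seed = as.integer(seed), n_chroms = as.integer(n_chroms),
              chrom_length = as.integer(chrom_length),
              n_genes = as.integer(n_genes),
              gene_length = as.integer(gene_length),
              flank = as.integer(flank),
              n_true_sites = as.integer(n_true_sites),
              fraction_sites_in_windows = fraction_sites_in_windows,
              site_width = as.integer(site_width), jitter_sd = jitter_sd,
              fp_rate = fp_rate, dropout_rate = dropout_rate,
              n_replicates = as.integer(n_replicates),
              ko_retention = ko_retention, t3_gain = t3_gain,
              p_up_given_bound = p_up_given_bound,
              effect_mean = effect_mean, effect_sd = effect_sd,
              ko_attenuation = ko_attenuation,
              min_gene_gap = as.integer(min_gene_gap),
              site_margin = as.integer(site_margin))
  probs <- c(fraction_sites_in_windows = cfg$fraction_sites_in_windows,
             dropout_rate = cfg$dropout_rate,
             ko_retention = cfg$ko_retention,
             p_up_given_bound = cfg$p_up_given_bound)
  bad <- names(probs)[probs < 0 | probs > 1]
  if (length(bad))
    stop("probabilities must be in [0,1]: ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (cfg$jitter_sd < 0) stop("jitter_sd must be >= 0", call. = FALSE)
  if (cfg$fp_rate < 0) stop("fp_rate must be >= 0", call. = FALSE)
  if (cfg$t3_gain < 0) stop("t3_gain must be >= 0", call. = FALSE)
  if (cfg$n_replicates < 1) stop("need >= 1 replicate", call. = FALSE)
  if (length(cfg$gene_length) != 2L || diff(cfg$gene_length) < 0)
    stop("gene_length must be a (min, max) pair", call. = FALSE)
  if (length(cfg$site_width) != 2L || diff(cfg$site_width) < 0)
    stop("site_width must be a (min, max) pair", call. = FALSE)
  if (cfg$site_width[1] < 16L + 2L)
    stop("site_width must accommodate a DR4 element (16 bp)",
         call. = FALSE)
  structure(cfg, class = "sim_config")
}

#' Read / write a simulation configuration (YAML)
#'
#' @param path YAML file path.
#' @return `read_sim_config` returns a [sim_config()]; `write_sim_config`
#'   returns `path` invisibly.
#' @export
read_sim_config <- function(path) {
  do.call(sim_config, yaml::read_yaml(path))
}

#' @rdname read_sim_config
#' @param config a [sim_config()].
#' @export
write_sim_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

SIM_SAMPLES <- data.frame(
  sample_id = c("WT_minusT3", "WT_plusT3", "KO_minusT3", "KO_plusT3"),
  genotype = c("wt", "wt", "ko", "ko"),
  treatment = c("minusT3", "plusT3", "minusT3", "plusT3"),
  stringsAsFactors = FALSE)

# internal: place non-overlapping genes whose +/-flank windows stay
# disjoint (pairwise gaps >= min_gene_gap between windows)
place_genes <- function(cfg) {
  per_chrom <- diff(round(seq(0, cfg$n_genes, length.out = cfg$n_chroms + 1)))
  out <- list()
  idx <- 0L
  for (ci in seq_len(cfg$n_chroms)) {
    k <- per_chrom[ci]
    if (k == 0) next
    chrom <- paste0("chr", ci)
    lens <- sample(seq(cfg$gene_length[1], cfg$gene_length[2]), k,
                   replace = TRUE)
    unit <- cfg$flank + cfg$min_gene_gap  # per-side reservation
    required <- sum(lens) + 2L * k * unit
    slack <- cfg$chrom_length - required
    if (slack < 0)
      stop("config infeasible: ", k, " genes (with ", cfg$flank,
           " bp flanks) do not fit a ", cfg$chrom_length,
           " bp chromosome", call. = FALSE)
    u <- stats::runif(k + 1L)
    extra <- floor(slack * u / sum(u))
    starts <- integer(k)
    pos <- 0L
    for (i in seq_len(k)) {
      pos <- pos + extra[i] + unit
      starts[i] <- pos
      pos <- pos + lens[i] + unit
    }
    out[[ci]] <- data.frame(
      gene_id = sprintf("gene_%04d", idx + seq_len(k)),
      name = sprintf("g%04d", idx + seq_len(k)),
      chrom = chrom, start = starts, end = starts + lens,
      strand = sample(c("+", "-"), k, replace = TRUE),
      stringsAsFactors = FALSE)
    idx <- idx + k
  }
  do.call(rbind, out)
}

# internal: plant binding sites — genic ones inside distinct gene
# windows, intergenic ones clear of every window
place_sites <- function(cfg, genes, windows) {
  n_genic <- round(cfg$fraction_sites_in_windows * cfg$n_true_sites)
  n_inter <- cfg$n_true_sites - n_genic
  if (n_genic > nrow(genes))
    stop("config infeasible: ", n_genic,
         " genic sites requested but only ", nrow(genes), " genes",
         call. = FALSE)
  widths <- sample(seq(cfg$site_width[1], cfg$site_width[2]),
                   cfg$n_true_sites, replace = TRUE)
  margin <- cfg$site_margin

  host_rows <- sample(seq_len(nrow(genes)), n_genic)
  genic <- lapply(seq_len(n_genic), function(i) {
    g <- host_rows[i]
    w <- widths[i]
    win <- windows[windows$gene_id == genes$gene_id[g], ]
    lo <- win$start + margin
    hi <- win$end - margin - w
    s <- lo + floor(stats::runif(1) * (hi - lo + 1L))
    data.frame(chrom = win$chrom, start = s, end = s + w,
               gene_id = genes$gene_id[g], genic = TRUE,
               stringsAsFactors = FALSE)
  })

  chrom_sizes <- stats::setNames(rep(cfg$chrom_length, cfg$n_chroms),
                                 paste0("chr", seq_len(cfg$n_chroms)))
  expanded <- data.frame(chrom = windows$chrom,
                         start = pmax(0L, windows$start - margin),
                         end = pmin(windows$end + margin,
                                    cfg$chrom_length))
  free <- complement_intervals(expanded, chrom_sizes)
  placed <- list()
  inter <- lapply(seq_len(n_inter), function(i) {
    w <- widths[n_genic + i]
    for (try in seq_len(1000L)) {
      avail <- free$end - free$start - w - 2L * margin
      ok <- which(avail >= 0)
      if (length(ok) == 0)
        stop("config infeasible: no intergenic space for sites",
             call. = FALSE)
      gi <- ok[sample.int(length(ok), 1L, prob = avail[ok] + 1)]
      s <- free$start[gi] + margin +
        floor(stats::runif(1) * (avail[gi] + 1))
      cand <- c(free$chrom[gi], s, s + w)
      clash <- any(vapply(placed, function(p) {
        p[1] == cand[1] &&
          as.integer(cand[2]) < as.integer(p[3]) + margin &&
          as.integer(p[2]) < as.integer(cand[3]) + margin
      }, logical(1)))
      if (!clash) {
        placed[[length(placed) + 1L]] <<- cand
        return(data.frame(chrom = cand[1], start = as.integer(cand[2]),
                          end = as.integer(cand[3]),
                          gene_id = NA_character_, genic = FALSE,
                          stringsAsFactors = FALSE))
      }
    }
    stop("config infeasible: could not place intergenic sites",
         call. = FALSE)
  })

  sites <- do.call(rbind, c(genic, inter))
  sites <- sort_intervals(sites)
  sites$site_id <- sprintf("site_%04d", seq_len(nrow(sites)))
  # T3-dependent margin: constitutive core plus extra +T3-only sites
  n_const <- round(nrow(sites) / (1 + cfg$t3_gain))
  t3_only_rows <- sample(seq_len(nrow(sites)), nrow(sites) - n_const)
  sites$t3_only <- seq_len(nrow(sites)) %in% t3_only_rows
  sites$ko_retained <- stats::rbinom(nrow(sites), 1L,
                                     cfg$ko_retention) == 1L
  sites$height <- stats::runif(nrow(sites), 5, 50)
  sites
}

# internal: i.i.d. uniform ACGT genome with RGGTCA-N4-RGGTCA elements
# instantiated at each site's centre (planting done on the letter vector
# before collapsing, so large genomes stay cheap)
make_genome <- function(cfg, sites) {
  chroms <- paste0("chr", seq_len(cfg$n_chroms))
  tre_start <- integer(nrow(sites))
  genome <- vapply(chroms, function(ch) {
    letters <- sample(c("A", "C", "G", "T"), cfg$chrom_length,
                      replace = TRUE)
    rows <- which(sites$chrom == ch)
    for (i in rows) {
      el <- c(sample(c("A", "G"), 1), "G", "G", "T", "C", "A",
              sample(c("A", "C", "G", "T"), 4, replace = TRUE),
              sample(c("A", "G"), 1), "G", "G", "T", "C", "A")
      s <- sites$start[i] + (sites$end[i] - sites$start[i] - 16L) %/% 2L
      letters[(s + 1L):(s + 16L)] <- el
      tre_start[i] <<- s
    }
    paste(letters, collapse = "")
  }, character(1))
  list(genome = genome, tre_start = tre_start)
}

# internal: detectable site ids per sample
detectable_sites <- function(sites, cfg) {
  const <- !sites$t3_only
  list(WT_minusT3 = sites$site_id[const],
       WT_plusT3 = sites$site_id,
       KO_minusT3 = sites$site_id[const & sites$ko_retained],
       KO_plusT3 = sites$site_id[sites$ko_retained])
}

# internal: one replicate's noisy peak calls for a detectable site set
sim_replicate_peaks <- function(det, cfg, sample_id, replicate_id) {
  n <- nrow(det)
  keep <- if (n) stats::rbinom(n, 1L, 1 - cfg$dropout_rate) == 1L else logical(0)
  jit <- matrix(round(stats::rnorm(2L * n, 0, cfg$jitter_sd)),
                ncol = 2L)
  s <- det$start + jit[, 1L]
  e <- det$end + jit[, 2L]
  narrow <- which(e - s < 50L)
  if (length(narrow)) {
    mid <- (s[narrow] + e[narrow]) %/% 2L
    s[narrow] <- mid - 25L
    e[narrow] <- mid + 25L
  }
  s <- pmax(0L, s)
  e <- pmax(e, s + 50L)
  e <- pmin(e, cfg$chrom_length)
  s <- pmin(s, e - 50L)
  h <- det$height * exp(stats::rnorm(n, 0, 0.2))
  true_peaks <- data.frame(chrom = det$chrom, start = as.integer(s),
                           end = as.integer(e), height = round(h, 3),
                           stringsAsFactors = FALSE)[keep, , drop = FALSE]

  n_fp <- stats::rpois(1L, cfg$fp_rate * n)
  if (n_fp > 0) {
    fp_chrom <- paste0("chr", sample.int(cfg$n_chroms, n_fp,
                                         replace = TRUE))
    fp_w <- sample(seq(cfg$site_width[1], cfg$site_width[2]), n_fp,
                   replace = TRUE)
    fp_s <- floor(stats::runif(n_fp) * (cfg$chrom_length - fp_w))
    fp <- data.frame(chrom = fp_chrom, start = as.integer(fp_s),
                     end = as.integer(fp_s + fp_w),
                     height = round(stats::runif(n_fp, 2, 8), 3),
                     stringsAsFactors = FALSE)
    true_peaks <- rbind(true_peaks, fp)
  }
  if (nrow(true_peaks) == 0) return(empty_peaks())
  out <- as_peaks(sort_intervals(true_peaks))
  out$name <- sprintf("%s_%s_peak_%d", sample_id, replicate_id,
                      seq_len(nrow(out)))
  out$score <- round(pmin(1000, out$height * 10))
  out$summit_offset <- (out$end - out$start) %/% 2L
  out$sample_id <- sample_id
  out$replicate_id <- replicate_id
  out
}

#' Simulate a synthetic TR ChIP-Seq study
#'
#' Generates, from a single seed, an i.i.d. uniform ACGT genome with a
#' DR4 element embedded at each planted binding site, non-overlapping
#' gene models, per-sample per-replicate noisy peak calls for the four
#' samples (wild type and TRalpha knockout, each with and without T3),
#' a linked expression table, and a truth record for recovery analysis.
#' Identical seeds give byte-identical output trees.
#'
#' @param config a [sim_config()].
#' @param dir output directory; created if needed.  When `NULL`, nothing
#'   is written and only in-memory objects are returned.
#' @return List with `genome` (named character), `genes`, `sites`,
#'   `peaks` (nested list `sample -> replicate -> peak frame`),
#'   `expression`, `truth` (list: `config`, `sites`, `detectable`,
#'   `bound_genes`, `wt_up_genes`, `samples`) and `paths` (written
#'   files, or `NULL`).
#' @export
simulate_tr_chipseq <- function(config, dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  set.seed(cfg$seed)

  genes <- place_genes(cfg)
  chrom_sizes <- stats::setNames(rep(cfg$chrom_length, cfg$n_chroms),
                                 paste0("chr", seq_len(cfg$n_chroms)))
  windows <- build_windows(genes, flank = cfg$flank,
                           chrom_sizes = chrom_sizes)
  sites <- place_sites(cfg, genes, windows)

  planted <- make_genome(cfg, sites)
  genome <- planted$genome
  sites$tre_start <- planted$tre_start

  det <- detectable_sites(sites, cfg)
  peaks <- list()
  for (si in seq_len(nrow(SIM_SAMPLES))) {
    sample_id <- SIM_SAMPLES$sample_id[si]
    det_sites <- sites[sites$site_id %in% det[[sample_id]], , drop = FALSE]
    reps <- list()
    for (r in seq_len(cfg$n_replicates)) {
      rid <- paste0("rep", r)
      reps[[rid]] <- sim_replicate_peaks(det_sites, cfg, sample_id, rid)
    }
    peaks[[sample_id]] <- reps
  }

  bound_genes <- lapply(det, function(ids) {
    sort(unique(stats::na.omit(sites$gene_id[sites$site_id %in% ids])))
  })

  # expression linked to wild-type binding (union over treatments)
  wt_bound <- bound_genes$WT_plusT3
  is_bound <- genes$gene_id %in% wt_bound
  up <- is_bound & stats::runif(nrow(genes)) < cfg$p_up_given_bound
  gene_site <- match(genes$gene_id, sites$gene_id)
  ko_retained_gene <- !is.na(gene_site) & sites$ko_retained[gene_site]

  log2fc_wt <- stats::rnorm(nrow(genes), 0, 0.1)
  fdr_wt <- stats::runif(nrow(genes))
  log2fc_wt[up] <- stats::rnorm(sum(up), cfg$effect_mean, cfg$effect_sd)
  fdr_wt[up] <- stats::runif(sum(up), 0, 0.01)
  log2fc_ko <- stats::rnorm(nrow(genes), 0, 0.1)
  fdr_ko <- stats::runif(nrow(genes))
  att <- up & ko_retained_gene
  log2fc_ko[att] <- cfg$ko_attenuation * log2fc_wt[att] +
    stats::rnorm(sum(att), 0, 0.1)
  fdr_ko[att] <- stats::runif(sum(att), 0, 0.01)
  expression <- data.frame(gene_id = genes$gene_id,
                           log2fc_wt = round(log2fc_wt, 4),
                           fdr_wt = round(fdr_wt, 6),
                           log2fc_ko = round(log2fc_ko, 4),
                           fdr_ko = round(fdr_ko, 6),
                           stringsAsFactors = FALSE)

  truth <- list(config = unclass(cfg), samples = SIM_SAMPLES,
                sites = sites, detectable = det,
                bound_genes = bound_genes,
                wt_up_genes = sort(genes$gene_id[up]))

  paths <- NULL
  if (!is.null(dir)) {
    dir.create(file.path(dir, "peaks"), recursive = TRUE,
               showWarnings = FALSE)
    paths <- list(genome = file.path(dir, "genome.fasta"),
                  annotation = file.path(dir, "genes.gff3"),
                  expression = file.path(dir, "expression.tsv"),
                  truth = file.path(dir, "truth.json"),
                  config = file.path(dir, "config.yaml"),
                  peaks = list())
    write_fasta(genome, paths$genome)
    write_gff3(genes, paths$annotation)
    write_tsv(expression, paths$expression)
    jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE,
                         digits = NA)
    write_sim_config(cfg, paths$config)
    for (sample_id in names(peaks)) {
      paths$peaks[[sample_id]] <- vapply(names(peaks[[sample_id]]),
        function(rid) {
          p <- file.path(dir, "peaks",
                         paste0(sample_id, "_", rid, ".narrowPeak"))
          write_narrowpeak(peaks[[sample_id]][[rid]], p)
          p
        }, character(1))
    }
  }

  list(genome = genome, genes = genes, sites = sites, peaks = peaks,
       expression = expression, truth = truth, paths = paths,
       chrom_sizes = chrom_sizes)
}

#' Read a truth record written by [simulate_tr_chipseq()]
#'
#' @param path `truth.json` path.
#' @return Truth list.
#' @export
read_truth <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Evaluate pipeline recovery against simulation truth
#'
#' A called consensus peak matches a true site iff they overlap by at
#' least one base.  Site precision is matched-called / called, site
#' recall is matched-true / true-detectable, per sample.  When called
#' bound-gene sets are supplied, gene-level precision/recall against the
#' truth bound-gene sets are reported as well.
#'
#' @param truth truth list (from [simulate_tr_chipseq()] or
#'   [read_truth()]).
#' @param consensus named list, sample id -> `consensus_peaks` object (or
#'   plain interval data frame of called regions).
#' @param bound_genes optional named list, sample id -> character vector
#'   of called bound genes.
#' @return Data frame, one row per sample: `sample_id`, `n_true`,
#'   `n_called`, `site_precision`, `site_recall`, and (when supplied)
#'   `gene_precision`, `gene_recall`.
#' @export
evaluate_recovery <- function(truth, consensus, bound_genes = NULL) {
  sites <- truth$sites
  rows <- lapply(names(consensus), function(sample_id) {
    ids <- truth$detectable[[sample_id]]
    true_sites <- sites[sites$site_id %in% ids, , drop = FALSE]
    called <- consensus[[sample_id]]
    called <- if (inherits(called, "consensus_peaks")) called$peaks else called
    n_true <- nrow(true_sites)
    n_called <- nrow(called)
    if (n_called > 0 && n_true > 0) {
      seqlev <- sort(unique(c(called$chrom, true_sites$chrom)))
      hit <- GenomicRanges::findOverlaps(gi_to_gr(called, seqlev),
                                         gi_to_gr(true_sites, seqlev))
      prec <- length(unique(S4Vectors::queryHits(hit))) / n_called
      rec <- length(unique(S4Vectors::subjectHits(hit))) / n_true
    } else {
      prec <- if (n_called == 0) NA_real_ else 0
      rec <- if (n_true == 0) NA_real_ else 0
    }
    row <- data.frame(sample_id = sample_id, n_true = n_true,
                      n_called = n_called, site_precision = prec,
                      site_recall = rec, stringsAsFactors = FALSE)
    if (!is.null(bound_genes)) {
      tg <- truth$bound_genes[[sample_id]]
      cg <- bound_genes[[sample_id]]
      row$gene_precision <- if (length(cg)) length(intersect(cg, tg)) /
        length(cg) else NA_real_
      row$gene_recall <- if (length(tg)) length(intersect(cg, tg)) /
        length(tg) else NA_real_
    }
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate sequenced fragments over planted sites
#'
#' Companion to [pileup_call()]: uniform background fragments at
#' `background_rate` per base plus `frags_per_site` fragments stacked on
#' each site (midpoints jittered within the site).  Uses the current RNG
#' state.
#'
#' @param sites interval data frame of true sites.
#' @param chrom_sizes named vector of chromosome lengths.
#' @param frags_per_site fragments per site.
#' @param frag_length fragment length (bases).
#' @param background_rate background fragments per base.
#' @return Interval data frame of fragments.
#' @export
simulate_fragments <- function(sites, chrom_sizes, frags_per_site = 60L,
                               frag_length = 100L,
                               background_rate = 0.0005) {
  out <- list()
  for (ch in names(chrom_sizes)) {
    L <- as.integer(chrom_sizes[[ch]])
    n_bg <- stats::rpois(1L, background_rate * L)
    if (n_bg > 0) {
      s <- floor(stats::runif(n_bg) * (L - frag_length))
      out[[length(out) + 1L]] <- data.frame(chrom = ch,
                                            start = as.integer(s),
                                            end = as.integer(s + frag_length))
    }
  }
  for (i in seq_len(nrow(sites))) {
    L <- as.integer(chrom_sizes[[sites$chrom[i]]])
    mid <- sites$start[i] +
      floor(stats::runif(frags_per_site) *
              (sites$end[i] - sites$start[i]))
    s <- pmax(0L, pmin(L - frag_length, as.integer(mid - frag_length %/% 2L)))
    out[[length(out) + 1L]] <- data.frame(chrom = sites$chrom[i],
                                          start = s,
                                          end = s + frag_length)
  }
  if (length(out) == 0)
    return(genomic_intervals(character(), integer(), integer()))
  sort_intervals(do.call(rbind, out))
}

#' Simulate gene-set term annotations
#'
#' Draws `n_terms` terms whose member genes are sampled uniformly from
#' the universe — a null annotation for calibration studies.  Uses the
#' current RNG state.
#'
#' @param universe character vector of gene ids.
#' @param n_terms number of terms.
#' @param size_range term size range (genes per term).
#' @return List of term annotations (as from [read_gmt()]).
#' @export
simulate_terms <- function(universe, n_terms = 200L,
                           size_range = c(10L, 50L)) {
  sizes <- sample(seq(size_range[1], size_range[2]), n_terms,
                  replace = TRUE)
  lapply(seq_len(n_terms), function(i) {
    list(term_id = sprintf("T%04d", i),
         term_name = sprintf("synthetic term %d", i),
         gene_ids = sort(sample(universe, min(sizes[i],
                                              length(universe)))))
  })
}
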