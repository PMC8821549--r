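# small, fast configuration used across simulator tests
small_config <- function(seed = 1, ...) {
  sim_config(seed = seed, n_chroms = 1L, chrom_length = 600000L,
             n_genes = 40L, n_true_sites = 50L, ...)
}

test_that("identical seeds give byte-identical output trees", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  simulate_tr_chipseq(small_config(seed = 42), dir = d1)
  simulate_tr_chipseq(small_config(seed = 42), dir = d2)
  f1 <- sort(list.files(d1, recursive = TRUE))
  f2 <- sort(list.files(d2, recursive = TRUE))
  expect_equal(f1, f2)
  for (f in f1) {
    expect_equal(unname(tools::md5sum(file.path(d1, f))),
                 unname(tools::md5sum(file.path(d2, f))),
                 info = f)
  }
  # a different seed changes the data
  d3 <- withr::local_tempdir()
  simulate_tr_chipseq(small_config(seed = 43), dir = d3)
  expect_false(identical(tools::md5sum(file.path(d1, "truth.json")),
                         tools::md5sum(file.path(d3, "truth.json"))))
})

test_that("genic/intergenic site allocation is deterministic before noise", {
  sim <- simulate_tr_chipseq(sim_config(seed = 2, n_chroms = 1,
                                        chrom_length = 1200000L,
                                        n_genes = 80L,
                                        n_true_sites = 100L,
                                        fraction_sites_in_windows = 0.6))
  expect_equal(sum(sim$sites$genic), 60)
  expect_equal(nrow(sim$sites), 100)

  # every planted genic site lies inside its host gene's window
  win <- build_windows(sim$genes, flank = sim$truth$config$flank)
  genic <- sim$sites[sim$sites$genic, ]
  m <- match(genic$gene_id, win$gene_id)
  expect_true(all(genic$start >= win$start[m] & genic$end <= win$end[m]))
  # intergenic sites overlap no window
  inter <- sim$sites[!sim$sites$genic, ]
  asn <- assign_peaks(inter[, c("chrom", "start", "end")], win)
  expect_true(all(asn$category == "not_annotated"))
  # each site carries one planted DR4 at its centre
  tre <- count_tres_in_peaks(sim$sites[, c("chrom", "start", "end")],
                             sim$genome)
  expect_true(all(tre$counts$n_hits >= 1))
})

test_that("noiseless simulation is recovered exactly by the pipeline", {
  sim <- simulate_tr_chipseq(small_config(seed = 7, jitter_sd = 0,
                                          dropout_rate = 0, fp_rate = 0))
  cp <- lapply(sim$peaks, intersect_replicates)
  win <- build_windows(sim$genes, flank = sim$truth$config$flank)
  bound <- lapply(cp, function(x) bound_gene_set(assign_peaks(x, win)))
  ev <- evaluate_recovery(sim$truth, cp, bound)
  expect_equal(ev$site_precision, rep(1, 4))
  expect_equal(ev$site_recall, rep(1, 4))
  expect_equal(ev$gene_precision, rep(1, 4))
  expect_equal(ev$gene_recall, rep(1, 4))
  # consensus equals the planted detectable sites exactly
  for (s in names(cp)) {
    truth_sites <- sim$sites[sim$sites$site_id %in%
                               sim$truth$detectable[[s]],
                             c("chrom", "start", "end")]
    truth_sites <- truth_sites[order(truth_sites$chrom,
                                     truth_sites$start), ]
    expect_equal(cp[[s]]$peaks[, c("chrom", "start", "end")],
                 truth_sites, ignore_attr = TRUE)
  }
})

test_that("sample detectability reflects treatment gain and knockout", {
  sim <- simulate_tr_chipseq(small_config(seed = 3))
  det <- sim$truth$detectable
  expect_true(all(det$WT_minusT3 %in% det$WT_plusT3))
  expect_true(all(det$KO_minusT3 %in% det$KO_plusT3))
  expect_true(all(det$KO_plusT3 %in% det$WT_plusT3))
  expect_setequal(det$KO_plusT3,
                  sim$sites$site_id[sim$sites$ko_retained])
  # +T3 gain: constitutive core is ~ n/(1 + t3_gain)
  expect_equal(length(det$WT_minusT3),
               round(nrow(sim$sites) / (1 + sim$truth$config$t3_gain)))
})

test_that("dropping every site in one replicate removes all consensus", {
  sim <- simulate_tr_chipseq(small_config(seed = 5))
  reps <- sim$peaks$WT_plusT3
  reps$rep2 <- reps$rep2[0, ]   # one replicate lost everything
  cp <- list(WT_plusT3 = intersect_replicates(reps))
  ev <- evaluate_recovery(sim$truth, cp)
  expect_equal(cp$WT_plusT3$peaks |> nrow(), 0)
  expect_equal(ev$site_recall, 0)
})

test_that("replicate intersection suppresses independent false peaks", {
  # false peaks must co-occur in all three replicates to survive, so
  # pooled over seeded 1 Mb runs at fp_rate = 0.5 nearly every consensus
  # peak matches a true site
  matched <- 0L
  called <- 0L
  for (seed in 1:20) {
    cfg <- sim_config(seed = seed, n_chroms = 1L, chrom_length = 1000000L,
                      n_genes = 60L, n_true_sites = 70L,
                      fp_rate = 0.5, dropout_rate = 0)
    sim <- simulate_tr_chipseq(cfg)
    cp <- lapply(sim$peaks, intersect_replicates)
    ev <- evaluate_recovery(sim$truth, cp)
    called <- called + sum(ev$n_called)
    matched <- matched + sum(round(ev$site_precision * ev$n_called))
    expect_equal(ev$site_recall, rep(1, 4))  # no dropout, jitter only
  }
  expect_gte(matched / called, 0.99)
})

test_that("infeasible configurations are rejected up front", {
  expect_error(simulate_tr_chipseq(sim_config(n_genes = 500L,
                                              chrom_length = 100000L,
                                              n_chroms = 1L)),
               "infeasible")
  expect_error(sim_config(dropout_rate = 1.5), "\\[0,1\\]")
  expect_error(sim_config(jitter_sd = -1), ">= 0")
})

test_that("simulated fragments drive the pileup caller end to end", {
  set.seed(31)
  sites <- data.frame(chrom = "chr1", start = c(20000L, 60000L),
                      end = c(20300L, 60250L))
  frags <- simulate_fragments(sites, c(chr1 = 100000L),
                              frags_per_site = 60, frag_length = 100,
                              background_rate = 0.0005)
  pk <- pileup_call(frags, c(chr1 = 100000L), background_rate = 0.0005)
  expect_equal(nrow(pk), 2)
  hit <- GenomicRanges::findOverlaps(
    GenomicRanges::GRanges("chr1", IRanges::IRanges(pk$start + 1, pk$end)),
    GenomicRanges::GRanges("chr1", IRanges::IRanges(sites$start + 1,
                                                    sites$end)))
  expect_equal(length(unique(S4Vectors::subjectHits(hit))), 2)
})

test_that("config YAML round-trips through read/write", {
  cfg <- small_config(seed = 9, fp_rate = 0.25)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_sim_config(cfg, path)
  expect_equal(read_sim_config(path), cfg)
})
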