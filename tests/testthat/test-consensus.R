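test_that("merge_intervals handles overlap, book-ended adjacency and gaps", {
  m <- merge_intervals(genomic_intervals("chr1", c(100, 150), c(200, 250)))
  expect_equal(m, genomic_intervals("chr1", 100, 250))

  adj <- merge_intervals(genomic_intervals("chr1", c(100, 200), c(200, 300)))
  expect_equal(adj, genomic_intervals("chr1", 100, 300))

  x <- genomic_intervals("chr1", c(100, 205), c(200, 300))
  expect_equal(merge_intervals(x, max_gap = 4), x)
  expect_equal(merge_intervals(x, max_gap = 5),
               genomic_intervals("chr1", 100, 300))
  expect_equal(merge_intervals(x, max_gap = 4), oracle_merge(x, 4),
               ignore_attr = TRUE)
  expect_equal(merge_intervals(x, max_gap = 5), oracle_merge(x, 5),
               ignore_attr = TRUE)

  expect_error(merge_intervals(x, max_gap = -1), "non-negative")
})

test_that("merge_intervals preserves covered bases and matches the oracle", {
  set.seed(101)
  for (rep in 1:10) {
    iv <- random_intervals(sample(1:40, 1))
    gap <- sample(0:30, 1)
    got <- merge_intervals(iv, max_gap = gap)
    expect_equal(got, oracle_merge(iv, gap), ignore_attr = TRUE)
    if (gap == 0) {
      cov <- oracle_base_cover(iv)
      expect_equal(sum(got$end - got$start),
                   sum(vapply(cov, sum, numeric(1))))
    }
  }
})

test_that("intersect_replicates finds mutually covered regions", {
  reps <- list(rep1 = genomic_intervals("chr1", 100, 200),
               rep2 = genomic_intervals("chr1", 150, 250),
               rep3 = genomic_intervals("chr1", 180, 220))
  cp <- intersect_replicates(reps)
  expect_equal(cp$peaks[, c("chrom", "start", "end")],
               genomic_intervals("chr1", 180, 200))
  expect_equal(nrow(cp$support), 3)
  expect_setequal(cp$support$replicate_id, c("rep1", "rep2", "rep3"))
})

test_that("single replicate gives its merged peaks; empty replicate absorbs", {
  one <- list(rep1 = genomic_intervals("chr1", c(100, 150, 500),
                                       c(200, 260, 600)))
  cp <- intersect_replicates(one)
  expect_equal(cp$peaks[, c("chrom", "start", "end")],
               genomic_intervals("chr1", c(100, 500), c(260, 600)))

  reps <- list(rep1 = genomic_intervals("chr1", 100, 200),
               rep2 = genomic_intervals(character(), integer(), integer()),
               rep3 = genomic_intervals("chr1", 100, 200))
  expect_equal(nrow(intersect_replicates(reps)$peaks), 0)

  expect_error(intersect_replicates(list()), "non-empty")
})

test_that("consensus height is min over replicates of max support height", {
  reps <- list(
    rep1 = data.frame(chrom = "chr1", start = c(100L, 140L),
                      end = c(160L, 210L), height = c(9, 4)),
    rep2 = data.frame(chrom = "chr1", start = 120L, end = 220L,
                      height = 6))
  cp <- intersect_replicates(reps)
  # region [120,210): rep1 contributes peaks with heights 9 and 4 (max 9),
  # rep2 contributes height 6 -> min(9, 6) = 6
  expect_equal(cp$peaks$height, 6)
})

test_that("replicate intersection matches the per-base oracle on random data", {
  set.seed(77)
  for (rep in 1:12) {
    R <- sample(1:4, 1)
    reps <- lapply(seq_len(R), function(i) random_intervals(sample(1:50, 1)))
    names(reps) <- paste0("rep", seq_len(R))
    got <- intersect_replicates(reps)$peaks[, c("chrom", "start", "end")]
    want <- oracle_consensus(reps)
    expect_equal(got, want, ignore_attr = TRUE)
  }
})

test_that("consensus coverage is monotone in peaks and replicates", {
  set.seed(33)
  covered <- function(x) if (nrow(x)) sum(x$end - x$start) else 0
  for (rep in 1:6) {
    reps <- lapply(1:3, function(i) random_intervals(sample(5:30, 1)))
    names(reps) <- paste0("rep", 1:3)
    base <- covered(intersect_replicates(reps)$peaks)

    # adding a peak to one replicate never shrinks consensus coverage
    more <- reps
    more[[1]] <- rbind(more[[1]], random_intervals(1))
    expect_gte(covered(intersect_replicates(more)$peaks), base)

    # removing a replicate weakens the support requirement
    fewer <- reps[1:2]
    expect_gte(covered(intersect_replicates(fewer)$peaks), base)

    # consensus is contained in each replicate's merged coverage
    cons <- intersect_replicates(reps)$peaks
    if (nrow(cons)) {
      for (p in reps) {
        cov <- oracle_base_cover(p)
        for (i in seq_len(nrow(cons))) {
          ch <- cons$chrom[i]
          expect_true(all(cov[[ch]][(cons$start[i] + 1):cons$end[i]]))
        }
      }
    }
  }
})

test_that("peak width summary counts all peaks and applies strict < 500", {
  pk <- genomic_intervals("chr1", c(0, 1000, 2000), c(100, 1300, 2600))
  s <- peak_width_summary(pk, bins = 500)
  expect_equal(sum(s$counts), 3)
  expect_equal(s$fraction_lt_500, 2 / 3)

  all499 <- genomic_intervals("chr1", c(0, 1000), c(499, 1499))
  expect_equal(peak_width_summary(all499, bins = 500)$fraction_lt_500, 1)

  exact <- genomic_intervals("chr1", 0, 500)
  expect_equal(peak_width_summary(exact, bins = 500)$fraction_lt_500, 0)

  expect_error(peak_width_summary(pk[0, ]), "empty")
  expect_error(peak_width_summary(pk, bins = c(500, 100)),
               "strictly increasing")
})

test_that("pileup_call recovers a stacked locus and honours its limits", {
  expect_error(pileup_call(genomic_intervals("chr1", 0, 10),
                           c(chr1 = 0), 0.001), "positive")
  expect_equal(nrow(pileup_call(genomic_intervals(character(), integer(),
                                                  integer()),
                                c(chr1 = 1000L), 0.001)), 0)

  # 60 fragments of length 100 stacked on one locus of a 100 kb chromosome
  frags <- genomic_intervals("chr1", rep(50000L, 60) + (0:59) %% 10,
                             rep(50100L, 60) + (0:59) %% 10)
  pk <- pileup_call(frags, c(chr1 = 100000L), background_rate = 0.001)
  expect_equal(nrow(pk), 1)
  expect_lte(pk$start, 50000)
  expect_gte(pk$end, 50109)
  # oracle: per-base Poisson tail with BH over the genome
  cov <- integer(100000L)
  for (i in seq_len(nrow(frags)))
    cov[(frags$start[i] + 1):frags$end[i]] <- cov[(frags$start[i] + 1):frags$end[i]] + 1L
  lambda <- 0.001 * 100
  p <- ppois(cov - 1, lambda, lower.tail = FALSE)
  adj <- oracle_bh(p)
  want <- oracle_runs(adj < 0.05, "chr1")
  expect_equal(pk$start, want$start)
  expect_equal(pk$end, want$end)
  expect_equal(pk$height, max(cov))
  expect_equal(pk$summit_offset, which.max(cov[(pk$start + 1):pk$end]) - 1L)
})

test_that("pileup_call limit behaviour: q_cutoff -> 0 and tiny background", {
  set.seed(9)
  frags <- random_intervals(30, chroms = "chr1", max_coord = 5000,
                            max_width = 200)
  expect_equal(nrow(pileup_call(frags, c(chr1 = 5000L), 0.001,
                                q_cutoff = 0)), 0)

  # background -> 0+: every covered run (coverage >= 1) is returned
  pk <- pileup_call(frags, c(chr1 = 5000L), background_rate = 1e-12,
                    q_cutoff = 0.05, max_gap = 0, min_width = 1)
  runs <- oracle_merge(frags[, c("chrom", "start", "end")], 0, span = 5000)
  expect_equal(pk[, c("chrom", "start", "end")], runs, ignore_attr = TRUE)

  # coverage equal to the background mean everywhere -> no peaks
  flat <- genomic_intervals("chr1", seq(0, 900, by = 100),
                            seq(100, 1000, by = 100))
  expect_equal(nrow(pileup_call(flat, c(chr1 = 1000L),
                                background_rate = 0.01)), 0)
})

test_that("weighted BH used by the caller agrees with stats::p.adjust", {
  set.seed(12)
  for (rep in 1:5) {
    p <- round(runif(8), 3)
    p[p == 0] <- 0.001
    count <- sample(1:5, 8, replace = TRUE)
    got <- trbound:::bh_adjust_weighted(p, count)
    want <- p.adjust(rep(p, count), "BH")[cumsum(count)]
    expect_equal(got, want)
  }
})
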