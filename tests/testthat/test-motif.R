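test_that("reverse complement is an IUPAC-aware involution", {
  expect_equal(reverse_complement("AGGTCA"), "TGACCT")
  expect_equal(reverse_complement("R"), "Y")
  expect_equal(reverse_complement(reverse_complement("ACGTN")), "ACGTN")
  expect_error(reverse_complement("ACGX"), "invalid character")
})

test_that("scan_dr4 finds the canonical DR4 with the degenerate first base", {
  h <- scan_dr4("AGGTCAACGTAGGTCA")
  expect_equal(nrow(h[h$strand == "+", ]), 1)
  expect_equal(h$start[h$strand == "+"], 0)
  expect_equal(h$half1_seq[h$strand == "+"], "AGGTCA")

  g <- scan_dr4("GGGTCAACGTGGGTCA")
  expect_equal(g$start[g$strand == "+"], 0)  # G accepted at R position

  # wrong spacer: no hits
  expect_equal(nrow(scan_dr4("AGGTCAACGAGGTCA")), 0)
  expect_error(scan_dr4("ACGT", spacer = -1), "non-negative")
})

test_that("minus-strand hits mirror plus-strand coordinates", {
  seq <- "AGGTCAACGTAGGTCA"
  rc <- reverse_complement(seq)
  h <- scan_dr4(rc)
  minus <- h[h$strand == "-", ]
  expect_equal(nrow(minus), 1)
  expect_equal(minus$start, nchar(seq) - 16)  # len - span
})

test_that("scan_dr4 matches the exhaustive oracle on random sequences", {
  set.seed(88)
  for (rep in 1:6) {
    # random background with a few planted elements so hits exist
    s <- random_dna(1500)
    for (pos in sample(seq(1, 1400, by = 120), 4)) {
      el <- paste0(sample(c("A", "G"), 1), "GGTCA",
                   random_dna(4), sample(c("A", "G"), 1), "GGTCA")
      substr(s, pos, pos + 15) <- el
    }
    got <- scan_dr4(s)
    want <- oracle_scan_dr4(s)
    want <- want[order(want$start, want$strand), ]
    expect_equal(got$start, want$start)
    expect_equal(got$strand, want$strand)

    # strand symmetry: scanning the reverse complement mirrors hits
    flip <- scan_dr4(reverse_complement(s))
    expect_equal(sort(nchar(s) - (flip$start + 16)), sort(got$start))
    expect_equal(sum(flip$strand == "-"), sum(got$strand == "+"))
    expect_equal(sum(flip$strand == "+"), sum(got$strand == "-"))
  }
})

test_that("mismatch allowance applies only at non-degenerate positions", {
  # one mismatch in the second half-site (T -> C at position 4)
  s <- "AGGTCAACGTAGGCCA"
  expect_equal(nrow(scan_dr4(s)), 0)
  h <- scan_dr4(s, max_mismatch = 1)
  h <- h[h$strand == "+", ]
  expect_equal(h$start, 0)
  expect_equal(h$mismatches, 1)
  # a pyrimidine at the degenerate R position never matches
  tg <- scan_dr4("TGGTCAACGTAGGTCA", max_mismatch = 1)
  expect_equal(nrow(tg[tg$strand == "+" & tg$start == 0, ]), 0)
  # N in the subject never matches a non-N pattern base
  expect_equal(nrow(scan_dr4("NGGTCAACGTAGGTCA")), 0)
})

test_that("DR4 frequency on random sequence matches the combinatorial rate", {
  set.seed(19)
  L <- 2000L
  n_seq <- 100L
  total <- sum(vapply(seq_len(n_seq), function(i) {
    nrow(scan_dr4(random_dna(L)))
  }, numeric(1)))
  p_half <- (2 / 4) * (1 / 4)^5          # P(RGGTCA at a position)
  expected <- n_seq * 2 * (L - 16 + 1) * p_half^2
  expect_lte(abs(total - expected), 4 * sqrt(expected))
})

test_that("count_tres_in_peaks shifts hits into the genomic frame", {
  genome <- c(chr1 = paste0(random_dna(100), "AGGTCAACGTAGGTCA",
                            random_dna(100)))
  peak <- genomic_intervals("chr1", 90, 130)
  res <- count_tres_in_peaks(peak, genome)
  expect_equal(res$total, 1)
  expect_equal(res$counts$n_hits, 1)
  expect_equal(res$hits$start[res$hits$strand == "+"], 100)

  none <- count_tres_in_peaks(genomic_intervals("chr1", 0, 60), genome)
  expect_equal(none$total, 0)

  expect_error(count_tres_in_peaks(genomic_intervals("chr1", 200, 300),
                                   genome), "beyond the end")
  expect_error(count_tres_in_peaks(genomic_intervals("chrX", 0, 10),
                                   genome), "absent from genome")
})

test_that("planted elements are counted exactly, summed over peaks", {
  set.seed(4)
  seqs <- character(10)
  for (i in 1:10) {
    s <- random_dna(400)
    for (pos in c(51, 201)) {
      el <- paste0("AGGTCA", random_dna(4), "GGGTCA")
      substr(s, pos, pos + 15) <- el
    }
    seqs[i] <- s
  }
  genome <- setNames(seqs, paste0("c", 1:10))
  peaks <- data.frame(chrom = paste0("c", 1:10), start = 0L, end = 400L)
  res <- count_tres_in_peaks(peaks, genome)
  expect_gte(res$total, 20)  # 2 planted per peak; chance extras possible
  expect_true(all(res$counts$n_hits >= 2))
})
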