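demo_records <- function() {
  data.frame(gene_id = c("g1", "g2", "g3", "g4", "g5"),
             log2fc_wt = c(1.0, log2(1.5), 1.0, -1.2, NA),
             fdr_wt = c(0.01, 0.01, 0.05, 0.001, 0.01),
             log2fc_ko = c(0.4, 0.1, NA, -0.6, 0),
             fdr_ko = c(0.2, 0.9, NA, 0.01, 0.5),
             stringsAsFactors = FALSE)
}

test_that("regulation cutoffs: inclusive fold change, strict FDR", {
  up <- select_regulated(demo_records(), "wt", "up")
  expect_true("g1" %in% up$gene_ids)          # 2-fold passes 1.5-fold
  expect_true("g2" %in% up$gene_ids)          # exactly log2(1.5): inclusive
  expect_false("g3" %in% up$gene_ids)         # fdr = 0.05 exactly: strict <
  expect_false("g5" %in% up$gene_ids)         # absent log2fc excluded

  down <- select_regulated(demo_records(), "wt", "down")
  expect_equal(down$gene_ids, "g4")

  expect_length(intersect(up$gene_ids, down$gene_ids), 0)
  expect_error(select_regulated(demo_records(), "wt", "up",
                                fold_cutoff = 1), "> 1")
})

test_that("venn reproduces the worked two-set arithmetic", {
  common <- sprintf("c%04d", 1:3022)
  a <- c(common, sprintf("a%04d", 1:286))    # 3308 TR-bound genes, -T3
  b <- c(common, sprintf("b%04d", 1:1297))   # 4319 TR-bound genes, +T3
  v <- venn(list(minusT3 = a, plusT3 = b))
  expect_equal(v$union_size, 4605)
  expect_equal(unname(v$regions),
               c(286, 1297, 3022))
  expect_equal(sum(v$regions), v$union_size)
})

test_that("venn handles disjoint, identical and three-set input", {
  d <- venn(list(A = "a", B = "b"))
  expect_equal(d$union_size, 2)
  expect_equal(unname(d$regions["A_and_B"]), 0)

  i <- venn(list(A = c("x", "y"), B = c("x", "y")))
  expect_equal(unname(i$regions[c("only_A", "only_B")]), c(0, 0))

  t <- venn(list(A = c("1", "2", "3"), B = c("2", "3", "4"),
                 C = c("3", "4", "5")))
  expect_length(t$regions, 7)
  expect_equal(sum(t$regions), t$union_size)
  expect_equal(t$union_size, 5)
  expect_equal(unname(t$regions["A_and_B_and_C"]), 1)

  expect_error(venn(list(a = "x")), "at least 2")
  expect_error(venn(list(a = "x", b = "y", c = "z", d = "w")),
               "unsupported")
})

test_that("inclusion-exclusion holds on random sets", {
  set.seed(14)
  for (rep in 1:10) {
    u <- sprintf("g%03d", 1:200)
    a <- sample(u, sample(10:150, 1))
    b <- sample(u, sample(10:150, 1))
    v <- venn(list(A = a, B = b))
    expect_equal(v$union_size,
                 length(a) + length(b) - length(intersect(a, b)))
    expect_equal(sum(v$regions), v$union_size)
  }
})

test_that("overlap percentages round half away from zero", {
  expect_equal(overlap_percent(896, 4605), 19L)
  expect_equal(overlap_percent(3129, 3327), 94L)
  expect_equal(overlap_percent(0, 10), 0L)
  expect_equal(overlap_percent(10, 10), 100L)
  expect_equal(overlap_percent(1, 8), 13L)    # 12.5 -> 13, half away from 0
  expect_error(overlap_percent(1, 0), "positive")
  expect_error(overlap_percent(5, 3), "part")
})

test_that("genotype partition blocks are disjoint and reconstruct the union", {
  wt <- sprintf("w%04d", 1:4605)
  ko <- c(wt[1:3129], sprintf("k%03d", 1:198))  # |KO| = 3327, common 3129
  p <- partition_by_genotype(wt, ko)
  expect_equal(length(p$wt_only$gene_ids), 1476)
  expect_equal(length(p$common$gene_ids), 3129)
  expect_equal(length(p$ko_only$gene_ids), 198)
  expect_length(intersect(p$wt_only$gene_ids, p$common$gene_ids), 0)
  expect_length(intersect(p$wt_only$gene_ids, p$ko_only$gene_ids), 0)
  expect_setequal(c(p$wt_only$gene_ids, p$common$gene_ids,
                    p$ko_only$gene_ids), union(wt, ko))

  same <- partition_by_genotype(c("a", "b"), c("a", "b"))
  expect_length(same$wt_only$gene_ids, 0)
  expect_length(same$ko_only$gene_ids, 0)
})

test_that("fold-change matrix lays out blocks with descending WT effect", {
  p <- partition_by_genotype(c("g1", "g2", "g9"), c("g2", "g4"))
  fcm <- fold_change_matrix(p, demo_records())
  expect_equal(nrow(fcm), 4)
  expect_equal(fcm$block, c("wt_only", "wt_only", "common", "ko_only"))
  # wt_only holds g1 (1.0) and g9 (absent -> NA last)
  expect_equal(fcm$gene_id[1:2], c("g1", "g9"))
  expect_true(is.na(fcm$log2fc_wt[2]) && is.na(fcm$log2fc_ko[2]))
  expect_equal(fcm$log2fc_wt[fcm$gene_id == "g2"], log2(1.5))
})
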