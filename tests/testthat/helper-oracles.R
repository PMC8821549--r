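# Brute-force reference implementations used to cross-check the package's
# interval, motif and enrichment routines.  They are deliberately naive
# (per-base counting, exhaustive offset scans, closed-form combinatorics)
# and independent of the code paths they verify.

# per-base covered set of a peak table, one logical vector per chromosome
oracle_base_cover <- function(x, span = 10000L) {
  chroms <- sort(unique(x$chrom))
  out <- lapply(chroms, function(ch) {
    v <- logical(span)
    sub <- x[x$chrom == ch, , drop = FALSE]
    for (i in seq_len(nrow(sub)))
      v[(sub$start[i] + 1L):sub$end[i]] <- TRUE
    v
  })
  names(out) <- chroms
  out
}

# runs of TRUE in a logical vector -> 0-based half-open intervals
oracle_runs <- function(v, chrom) {
  r <- rle(v)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values
  data.frame(chrom = rep(chrom, sum(keep)), start = starts[keep],
             end = ends[keep], stringsAsFactors = FALSE)
}

# merge oracle: mark covered bases, close gaps <= max_gap, emit runs
oracle_merge <- function(x, max_gap = 0L, span = 10000L) {
  cov <- oracle_base_cover(x, span)
  out <- lapply(names(cov), function(ch) {
    v <- cov[[ch]]
    if (max_gap > 0) {
      runs <- oracle_runs(v, ch)
      if (nrow(runs) > 1) {
        for (i in seq_len(nrow(runs) - 1L)) {
          gap <- runs$start[i + 1L] - runs$end[i]
          if (gap <= max_gap)
            v[(runs$end[i] + 1L):runs$start[i + 1L]] <- TRUE
        }
      }
    }
    oracle_runs(v, ch)
  })
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# consensus oracle: count replicates covering each base, emit runs where
# the count equals the number of replicates
oracle_consensus <- function(replicate_peaks, span = 10000L) {
  chroms <- sort(unique(unlist(lapply(replicate_peaks,
                                      function(p) p$chrom))))
  out <- lapply(chroms, function(ch) {
    count <- integer(span)
    for (p in replicate_peaks) {
      v <- logical(span)
      sub <- p[p$chrom == ch, , drop = FALSE]
      for (i in seq_len(nrow(sub)))
        v[(sub$start[i] + 1L):sub$end[i]] <- TRUE
      count <- count + v
    }
    oracle_runs(count == length(replicate_peaks), ch)
  })
  res <- do.call(rbind, out)
  if (is.null(res))
    return(data.frame(chrom = character(), start = integer(),
                      end = integer()))
  res <- res[order(res$chrom, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# exhaustive DR4 scan by direct string comparison at every offset on
# both strands, with an IUPAC lookup table independent of Biostrings
ORACLE_IUPAC <- list(A = "A", C = "C", G = "G", T = "T",
                     R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                     W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                     B = c("C", "G", "T"), D = c("A", "G", "T"),
                     H = c("A", "C", "T"), V = c("A", "C", "G"),
                     N = c("A", "C", "G", "T"))

oracle_rc <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N", R = "Y",
            Y = "R", S = "S", W = "W", K = "M", M = "K", B = "V",
            V = "B", D = "H", H = "D")
  paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
}

oracle_half_match <- function(obs, pattern) {
  oc <- strsplit(obs, "")[[1]]
  pc <- strsplit(pattern, "")[[1]]
  all(vapply(seq_along(pc), function(i) {
    if (oc[i] == "N") pc[i] == "N" else oc[i] %in% ORACLE_IUPAC[[pc[i]]]
  }, logical(1)))
}

oracle_scan_dr4 <- function(seq, pattern = "RGGTCA", spacer = 4L) {
  seq <- toupper(seq)
  L <- nchar(pattern)
  span <- 2L * L + spacer
  one_strand <- function(s) {
    n <- nchar(s)
    hits <- integer(0)
    for (off in seq_len(max(0L, n - span + 1L)) - 1L) {
      h1 <- substr(s, off + 1L, off + L)
      h2 <- substr(s, off + L + spacer + 1L, off + span)
      if (oracle_half_match(h1, pattern) && oracle_half_match(h2, pattern))
        hits <- c(hits, off)
    }
    hits
  }
  plus <- one_strand(seq)
  minus_rc <- one_strand(oracle_rc(seq))
  minus <- nchar(seq) - (minus_rc + span)
  data.frame(start = c(plus, minus),
             strand = c(rep("+", length(plus)), rep("-", length(minus))),
             stringsAsFactors = FALSE)
}

# closed-form hypergeometric upper tail via binomial coefficients
oracle_hypergeom <- function(k, K, n, N) {
  js <- k:min(n, K)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# textbook BH: adj_i = min over j with p_j >= p_i of p_j * m / rank_j
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- rev(cummin(rev(ps * m / seq_len(m))))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# all-pairs overlap assignment oracle
oracle_assign <- function(peaks, windows) {
  lapply(seq_len(nrow(peaks)), function(i) {
    hits <- character(0)
    for (j in seq_len(nrow(windows))) {
      if (peaks$chrom[i] == windows$chrom[j] &&
          peaks$start[i] < windows$end[j] &&
          windows$start[j] < peaks$end[i])
        hits <- c(hits, windows$gene_id[j])
    }
    sort(unique(hits))
  })
}

# random interval tables for property tests
random_intervals <- function(n, chroms = c("chrA", "chrB", "chrC"),
                             max_coord = 10000L, max_width = 400L) {
  chrom <- sample(chroms, n, replace = TRUE)
  start <- sample.int(max_coord - max_width, n) - 1L
  width <- sample.int(max_width, n)
  data.frame(chrom = chrom, start = start, end = start + width,
             height = round(runif(n, 1, 20), 2),
             stringsAsFactors = FALSE)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
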