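IUPAC_LETTERS <- c("A", "C", "G", "T", "N", "R", "Y", "S", "W", "K", "M",
                   "B", "D", "H", "V")

check_alphabet <- function(seq, what = "sequence") {
  bad <- setdiff(unique(strsplit(toupper(seq), "")[[1]]), IUPAC_LETTERS)
  if (length(bad))
    stop("invalid character(s) in ", what, ": ",
         paste(bad, collapse = ", "), call. = FALSE)
  invisible(TRUE)
}

#' Reverse complement with IUPAC support
#'
#' An involution over the IUPAC nucleotide alphabet: degenerate codes are
#' complemented class-wise (R <-> Y, K <-> M, ...).
#'
#' @param seq single DNA string.
#' @return The reverse complement.
#' @examples
#' reverse_complement("AGGTCA")  # "TGACCT"
#' @export
reverse_complement <- function(seq) {
  if (length(seq) != 1L || !is.character(seq))
    stop("seq must be a single character string", call. = FALSE)
  seq <- toupper(seq)
  if (!nzchar(seq)) return(seq)
  check_alphabet(seq)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

# expand one IUPAC code to its base set
iupac_bases <- function(code) {
  strsplit(Biostrings::IUPAC_CODE_MAP[[code]], "")[[1]]
}

# internal: does `observed` half-site match `pattern`, allowing up to
# max_mismatch mismatches at non-degenerate pattern positions only?
# Degenerate positions must match their IUPAC class; N in the subject
# never matches a non-N pattern base.
half_site_match <- function(observed, pattern_chars, degenerate,
                            max_mismatch) {
  obs <- strsplit(observed, "")[[1]]
  if (length(obs) != length(pattern_chars)) return(NA_integer_)
  mm <- 0L
  for (i in seq_along(obs)) {
    pc <- pattern_chars[i]
    ok <- if (obs[i] == "N") pc == "N" else obs[i] %in% iupac_bases(pc)
    if (!ok) {
      if (degenerate[i]) return(NA_integer_)  # degenerate must match
      mm <- mm + 1L
      if (mm > max_mismatch) return(NA_integer_)
    }
  }
  mm
}

# internal: 0-based start offsets + mismatch counts of half-site matches
# on the plus strand of `seq`
half_site_hits <- function(seq, pattern, max_mismatch) {
  L <- nchar(pattern)
  if (nchar(seq) < L)
    return(data.frame(start = integer(), mismatches = integer()))
  subject <- Biostrings::DNAString(seq)
  m <- Biostrings::matchPattern(pattern, subject,
                                max.mismatch = max_mismatch,
                                fixed = "subject")
  starts0 <- Biostrings::start(m) - 1L
  if (length(starts0) == 0)
    return(data.frame(start = integer(), mismatches = integer()))
  pat_chars <- strsplit(toupper(pattern), "")[[1]]
  degenerate <- !(pat_chars %in% c("A", "C", "G", "T"))
  mism <- vapply(starts0, function(s) {
    half_site_match(substr(seq, s + 1L, s + L), pat_chars, degenerate,
                    max_mismatch)
  }, integer(1))
  keep <- !is.na(mism)
  data.frame(start = starts0[keep], mismatches = mism[keep])
}

#' Scan for DR4 thyroid-hormone response elements
#'
#' Finds direct repeats of a half-site pattern (default `"RGGTCA"`, i.e.
#' (A/G)GGTCA) separated by a fixed spacer (default 4 unconstrained
#' bases) — the canonical DR4 element bound by TR-RXR.  Both strands are
#' scanned by default; minus-strand hits are reported in plus-strand
#' coordinates of their leftmost base.  Overlapping and nested hits are
#' all reported.  Mismatches (up to `max_mismatch` per half-site) are
#' permitted only at non-degenerate pattern positions.
#'
#' @param seq single DNA string (or an element of a genome mapping).
#' @param pattern IUPAC half-site pattern.
#' @param max_mismatch mismatches allowed per half-site at non-degenerate
#'   positions.
#' @param spacer bases between the two half-sites (>= 0).
#' @param both_strands scan the reverse complement as well?
#' @param seqname optional sequence name stored in the hits.
#' @return Data frame `seqname`, `start` (0-based offset of the leftmost
#'   base), `strand`, `spacer`, `half1_seq`, `half2_seq`, `mismatches`,
#'   ordered by position then strand (`+` before `-`).  The hit span is
#'   `2 * nchar(pattern) + spacer`.
#' @examples
#' scan_dr4("AGGTCAACGTAGGTCA")  # one plus-strand hit at 0
#' @export
scan_dr4 <- function(seq, pattern = "RGGTCA", max_mismatch = 0L,
                     spacer = 4L, both_strands = TRUE, seqname = NA_character_) {
  if (length(spacer) != 1L || is.na(spacer) || spacer < 0)
    stop("spacer must be a single non-negative integer", call. = FALSE)
  if (max_mismatch < 0) stop("max_mismatch must be >= 0", call. = FALSE)
  if (!nzchar(pattern)) stop("pattern must be non-empty", call. = FALSE)
  check_alphabet(pattern, "pattern")
  seq <- toupper(seq)
  check_alphabet(seq)
  L <- nchar(pattern)
  span <- 2L * L + as.integer(spacer)

  scan_strand <- function(s) {
    hs <- half_site_hits(s, pattern, max_mismatch)
    if (nrow(hs) == 0)
      return(data.frame(start = integer(), half1_seq = character(),
                        half2_seq = character(), mismatches = integer()))
    idx <- match(hs$start + L + as.integer(spacer), hs$start)
    keep <- which(!is.na(idx))
    if (length(keep) == 0)
      return(data.frame(start = integer(), half1_seq = character(),
                        half2_seq = character(), mismatches = integer()))
    st <- hs$start[keep]
    data.frame(start = st,
               half1_seq = substring(s, st + 1L, st + L),
               half2_seq = substring(s, st + L + spacer + 1L, st + span),
               mismatches = hs$mismatches[keep] + hs$mismatches[idx[keep]],
               stringsAsFactors = FALSE)
  }

  plus <- scan_strand(seq)
  plus$strand <- rep("+", nrow(plus))
  hits <- plus
  if (both_strands) {
    rc <- reverse_complement(seq)
    minus <- scan_strand(rc)
    minus$strand <- rep("-", nrow(minus))
    # map to plus-strand coordinate of the leftmost base
    minus$start <- nchar(seq) - (minus$start + span)
    hits <- rbind(plus, minus)
  }
  hits <- hits[order(hits$start, hits$strand), , drop = FALSE]
  rownames(hits) <- NULL
  data.frame(seqname = rep(seqname, nrow(hits)), start = hits$start,
             strand = hits$strand, spacer = rep(as.integer(spacer),
                                                nrow(hits)),
             half1_seq = hits$half1_seq, half2_seq = hits$half2_seq,
             mismatches = hits$mismatches, stringsAsFactors = FALSE)
}

#' Count DR4 elements within peaks
#'
#' Extracts each peak's subsequence from the genome, runs [scan_dr4()],
#' and shifts hit coordinates into the genomic frame.
#'
#' @param peaks `consensus_peaks` object or interval data frame.
#' @param genome named character vector, chromosome name -> sequence.
#' @param pattern,max_mismatch,spacer,both_strands passed to [scan_dr4()].
#' @return List with `counts` (data frame `consensus_peak_id`, `chrom`,
#'   `start`, `end`, `n_hits`), `hits` (genomic-frame hit data frame) and
#'   `total`.
#' @export
count_tres_in_peaks <- function(peaks, genome, pattern = "RGGTCA",
                                max_mismatch = 0L, spacer = 4L,
                                both_strands = TRUE) {
  x <- peak_frame(peaks)
  unknown <- setdiff(unique(x$chrom), names(genome))
  if (length(unknown))
    stop("peak chromosome(s) absent from genome: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  over <- which(x$end > nchar(genome[x$chrom]))
  if (length(over))
    stop("peak ", x$consensus_id[over[1]], " extends beyond the end of ",
         x$chrom[over[1]], call. = FALSE)
  hit_list <- vector("list", nrow(x))
  n_hits <- integer(nrow(x))
  for (i in seq_len(nrow(x))) {
    sub <- substr(genome[[x$chrom[i]]], x$start[i] + 1L, x$end[i])
    h <- scan_dr4(sub, pattern = pattern, max_mismatch = max_mismatch,
                  spacer = spacer, both_strands = both_strands,
                  seqname = x$chrom[i])
    if (nrow(h)) {
      h$start <- h$start + x$start[i]
      h$consensus_peak_id <- x$consensus_id[i]
    } else {
      h$consensus_peak_id <- character(0)
    }
    hit_list[[i]] <- h
    n_hits[i] <- nrow(h)
  }
  counts <- data.frame(consensus_peak_id = x$consensus_id, chrom = x$chrom,
                       start = x$start, end = x$end, n_hits = n_hits,
                       stringsAsFactors = FALSE)
  hits <- do.call(rbind, hit_list)
  rownames(hits) <- NULL
  list(counts = counts, hits = hits, total = sum(n_hits))
}

#' Write motif hits as BED6
#'
#' The name field is `half1` + spacer bases placeholder + `half2`; score
#' is 0 and the strand column carries the hit strand.
#'
#' @param hits genomic-frame hit data frame (from
#'   [count_tres_in_peaks()]`$hits` or [scan_dr4()] with genomic
#'   coordinates).
#' @param path output path.
#' @param pattern_length half-site length used for the scan.
#' @return Invisibly, `path`.
#' @export
write_motif_bed <- function(hits, path, pattern_length = 6L) {
  span <- 2L * pattern_length + hits$spacer
  out <- data.frame(chrom = hits$seqname, start = hits$start,
                    end = hits$start + span,
                    name = paste0(hits$half1_seq, ".", hits$spacer, ".",
                                  hits$half2_seq),
                    score = 0L, strand = hits$strand,
                    stringsAsFactors = FALSE)
  write_bed(out, path)
}
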