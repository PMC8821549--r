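#' Read peak calls from narrowPeak or BED files
#'
#' Parses MACS2-style narrowPeak (BED6+4) or plain BED (3-6 column) files
#' into a peak data frame.  Coordinates are kept exactly as in the file
#' (0-based half-open).  For narrowPeak, column 7 (signalValue) becomes
#' `height` and column 10 (summit offset from start) becomes
#' `summit_offset`, with the `-1` sentinel mapped to `NA`.  For BED input
#' `height` is 0.  Records are returned sorted by (chrom, start, end).
#'
#' @param path file path.
#' @param format `"narrowPeak"` or `"bed"`.
#' @param sample_id,replicate_id optional labels attached to every record.
#' @return Data frame with columns `chrom`, `start`, `end`, `name`,
#'   `score`, `strand`, `height`, `p_value`, `q_value`, `summit_offset`,
#'   `sample_id`, `replicate_id`.
#' @export
read_peaks <- function(path, format = c("narrowPeak", "bed"),
                       sample_id = NA_character_,
                       replicate_id = NA_character_) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0) return(empty_peaks())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (format == "narrowPeak") {
    bad <- which(nf != 10L)
    if (length(bad))
      stop("malformed narrowPeak line ", lineno[bad[1]], " in ", path,
           ": expected 10 tab-separated columns, found ", nf[bad[1]],
           call. = FALSE)
  } else {
    bad <- which(nf < 3L | nf > 6L)
    if (length(bad))
      stop("malformed BED line ", lineno[bad[1]], " in ", path,
           ": expected 3-6 tab-separated columns, found ", nf[bad[1]],
           call. = FALSE)
  }
  get <- function(i, default = NA_character_) {
    vapply(fields, function(f) if (length(f) >= i) f[[i]] else default,
           character(1))
  }
  num <- function(v, col) {
    out <- suppressWarnings(as.numeric(v))
    bad <- which(is.na(out) & !is.na(v))
    if (length(bad))
      stop("malformed line ", lineno[bad[1]], " in ", path,
           ": non-numeric value '", v[bad[1]], "' in column ", col,
           call. = FALSE)
    out
  }
  chrom <- get(1)
  start <- as.integer(num(get(2), 2))
  end <- as.integer(num(get(3), 3))
  bad <- which(start >= end)
  if (length(bad))
    stop("malformed line ", lineno[bad[1]], " in ", path,
         ": start >= end (", start[bad[1]], " >= ", end[bad[1]], ")",
         call. = FALSE)
  name <- get(4)
  score <- if (any(nf >= 5L)) num(get(5, "0"), 5) else rep(0, length(chrom))
  strand <- get(6, ".")
  strand[is.na(strand)] <- "."
  if (format == "narrowPeak") {
    height <- num(get(7), 7)
    p_value <- num(get(8), 8)
    q_value <- num(get(9), 9)
    summit <- as.integer(num(get(10), 10))
    summit[summit < 0L] <- NA_integer_
    bad <- which(!is.na(summit) & summit >= end - start)
    if (length(bad))
      stop("malformed line ", lineno[bad[1]], " in ", path,
           ": summit offset outside peak", call. = FALSE)
  } else {
    height <- rep(0, length(chrom))
    p_value <- q_value <- rep(NA_real_, length(chrom))
    summit <- rep(NA_integer_, length(chrom))
  }
  x <- data.frame(chrom = chrom, start = start, end = end,
                  name = name, score = score, strand = strand,
                  height = height, p_value = p_value, q_value = q_value,
                  summit_offset = summit,
                  sample_id = sample_id, replicate_id = replicate_id,
                  stringsAsFactors = FALSE)
  if (any(x$height < 0, na.rm = TRUE))
    stop("negative peak height in ", path, call. = FALSE)
  validate_intervals(x, "peak")
  sort_intervals(x)
}

empty_peaks <- function() {
  data.frame(chrom = character(), start = integer(), end = integer(),
             name = character(), score = numeric(), strand = character(),
             height = numeric(), p_value = numeric(), q_value = numeric(),
             summit_offset = integer(), sample_id = character(),
             replicate_id = character(), stringsAsFactors = FALSE)
}

# internal: fill peak-frame defaults from a minimal interval frame
as_peaks <- function(x) {
  n <- nrow(x)
  defaults <- list(name = NA_character_, score = 0, strand = ".",
                   height = 0, p_value = NA_real_, q_value = NA_real_,
                   summit_offset = NA_integer_, sample_id = NA_character_,
                   replicate_id = NA_character_)
  for (col in names(defaults))
    if (!col %in% names(x)) x[[col]] <- rep(defaults[[col]], n)
  x[, c("chrom", "start", "end", names(defaults)), drop = FALSE]
}

#' Write intervals or peaks as BED
#'
#' Writes 3 or 6 columns depending on whether `name`/`score`/`strand` are
#' present.  Output is sorted (chrom lexicographic, then start).
#'
#' @param x interval data frame.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_bed <- function(x, path) {
  validate_intervals(x)
  x <- sort_intervals(x)
  if (all(c("name", "score", "strand") %in% names(x))) {
    out <- data.frame(x$chrom, x$start, x$end, x$name,
                      as.character(x$score), x$strand)
  } else {
    out <- data.frame(x$chrom, x$start, x$end)
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write peaks in narrowPeak format
#'
#' Inverse of [read_peaks()] for `format = "narrowPeak"`: `height` goes to
#' the signalValue column and absent summits are written as `-1`.
#'
#' @param peaks peak data frame (see [read_peaks()]).
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_narrowpeak <- function(peaks, path) {
  validate_intervals(peaks, "peak")
  peaks <- sort_intervals(peaks)
  n <- nrow(peaks)
  col <- function(nm, default) {
    if (nm %in% names(peaks)) peaks[[nm]] else rep(default, n)
  }
  summit <- col("summit_offset", NA_integer_)
  summit[is.na(summit)] <- -1L
  strand <- col("strand", ".")
  strand[is.na(strand)] <- "."
  nm <- col("name", NA_character_)
  nm[is.na(nm)] <- sprintf("peak_%d", seq_len(n))[is.na(nm)]
  out <- data.frame(peaks$chrom, peaks$start, peaks$end, nm,
                    as.character(round(col("score", 0))), strand,
                    as.character(col("height", 0)),
                    as.character(ifelse(is.na(col("p_value", -1)), -1,
                                        col("p_value", -1))),
                    as.character(ifelse(is.na(col("q_value", -1)), -1,
                                        col("q_value", -1))),
                    summit)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
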