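#' Upper-tail hypergeometric probability
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: the probability of
#' drawing at least `k` annotated genes when sampling `n` genes without
#' replacement from a background of `N` genes of which `K` carry the
#' annotation.  Computed with the stable tail routine of
#' [stats::phyper()].
#'
#' @param k observed overlap (`0 <= k <= min(n, K)`).
#' @param K annotated genes in the background.
#' @param n query size.
#' @param N background size.
#' @return Probability in (0, 1].
#' @export
hypergeom_p <- function(k, K, n, N) {
  if (any(is.na(c(k, K, n, N))) || N < 0 || K < 0 || n < 0 || k < 0 ||
      K > N || n > N || k > min(n, K))
    stop("inconsistent counts: need 0 <= K,n <= N and 0 <= k <= min(n,K)",
         call. = FALSE)
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjusted values
#'
#' Standard BH step-up adjustment with monotonicity enforcement, mapped
#' back to the input order.  Wraps [stats::p.adjust()] after validating
#' that every p-value lies in (0, 1].
#'
#' @param p_values numeric vector of p-values in (0, 1].
#' @return Adjusted values in input order.
#' @export
bh_fdr <- function(p_values) {
  if (length(p_values) == 0) return(numeric())
  if (any(is.na(p_values)) || any(p_values <= 0) || any(p_values > 1))
    stop("p-values must lie in (0, 1]", call. = FALSE)
  stats::p.adjust(p_values, method = "BH")
}

#' Hypergeometric term enrichment over a gene set
#'
#' Tests each term for over-representation in the query relative to the
#' background: terms are intersected with the background before counting
#' (terms left empty are dropped), the one-sided hypergeometric p-value
#' is computed per term, and BH-FDR is applied across the reported terms.
#' Results are sorted by FDR, then p-value, then term id (a stable tie
#' order).
#'
#' @param query [gene_set()] or character vector; must be a subset of the
#'   background.
#' @param background [gene_set()] or character vector (the gene
#'   universe).
#' @param terms list of term annotations (see [read_gmt()]).
#' @param fdr_threshold terms with `fdr < fdr_threshold` are flagged
#'   enriched.
#' @return Data frame (class `enrichment_result`) with columns
#'   `term_id`, `term_name`, `k`, `K`, `n`, `N`, `p_value`, `fdr`,
#'   `enriched`; the threshold is stored as attribute `"fdr_threshold"`.
#' @export
enrich <- function(query, background, terms, fdr_threshold = 0.05) {
  q <- set_ids(query)
  bg <- set_ids(background)
  offenders <- setdiff(q, bg)
  if (length(offenders))
    stop("query genes absent from background: ",
         paste(utils::head(offenders, 5L), collapse = ", "),
         if (length(offenders) > 5L) ", ...", call. = FALSE)
  N <- length(bg)
  n <- length(q)
  rows <- lapply(terms, function(t) {
    tg <- intersect(unique(t$gene_ids), bg)
    K <- length(tg)
    if (K == 0) return(NULL)
    k <- length(intersect(tg, q))
    data.frame(term_id = t$term_id, term_name = t$term_name,
               k = k, K = K, n = n, N = N,
               p_value = hypergeom_p(k, K, n, N),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) {
    out <- data.frame(term_id = character(), term_name = character(),
                      k = integer(), K = integer(), n = integer(),
                      N = integer(), p_value = numeric(), fdr = numeric(),
                      enriched = logical(), stringsAsFactors = FALSE)
  } else {
    out <- do.call(rbind, rows)
    out$fdr <- bh_fdr(out$p_value)
    out$enriched <- out$fdr < fdr_threshold
    out <- out[order(out$fdr, out$p_value, out$term_id), , drop = FALSE]
    rownames(out) <- NULL
  }
  attr(out, "fdr_threshold") <- fdr_threshold
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' Genotype-differential ("subtraction") enrichment
#'
#' Terms enriched in result A but not in result B — e.g. pathways
#' enriched among wild-type TR-bound genes after subtracting those also
#' enriched among knockout TR-bound genes.  Matching is by term id; A's
#' statistics and ranking are retained.
#'
#' @param enriched_a,enriched_b [enrich()] results computed at the same
#'   FDR threshold.
#' @return The rows of `enriched_a` that are enriched in A and whose
#'   term id is not enriched in B, in A's order.
#' @export
differential_enrichment <- function(enriched_a, enriched_b) {
  ta <- attr(enriched_a, "fdr_threshold")
  tb <- attr(enriched_b, "fdr_threshold")
  if (!is.null(ta) && !is.null(tb) && !isTRUE(all.equal(ta, tb)))
    warning("enrichment results were flagged at different FDR thresholds")
  b_terms <- enriched_b$term_id[enriched_b$enriched]
  out <- enriched_a[enriched_a$enriched &
                      !(enriched_a$term_id %in% b_terms), , drop = FALSE]
  rownames(out) <- NULL
  out
}
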