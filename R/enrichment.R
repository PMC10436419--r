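## Over-representation analysis (ORA) of a gene list against GMT gene sets
## with the hypergeometric upper-tail test and BH correction.

#' Hypergeometric over-representation analysis
#'
#' For each term, tests whether the study genes over-represent the term's
#' members within the universe: `p = P[X >= k]` with
#' `X ~ Hypergeometric(N, K, n)` where `N` is the universe size, `K` the
#' term size within the universe, `n` the study size and `k` the overlap.
#' One-sided (over-representation only); BH correction across tested terms.
#' Terms are intersected with the universe before testing. Study genes
#' outside the universe are dropped with a warning.
#'
#' @param study_genes character vector of study gene ids.
#' @param gmt named list of term member vectors, as [read_table()] with
#'   `schema = "gmt"`.
#' @param universe character vector of background gene ids (e.g. all genes
#'   passing [prefilter_counts()]).
#' @param padj_thr significance threshold applied to the BH-adjusted
#'   p-value for the `significant` flag.
#' @return data.frame `term`, `description`, `k`, `K`, `n`, `N`, `pvalue`,
#'   `padj`, `significant`, sorted by p-value. Empty study set gives an
#'   empty result.
#' @export
ora <- function(study_genes, gmt, universe, padj_thr = 0.05) {
  universe <- unique(universe)
  if (!length(universe)) stop("empty universe")
  study <- unique(study_genes)
  outside <- setdiff(study, universe)
  if (length(outside)) {
    warning(length(outside), " study gene(s) outside the universe dropped")
    study <- intersect(study, universe)
  }
  empty <- data.frame(term = character(), description = character(),
                      k = integer(), K = integer(), n = integer(),
                      N = integer(), pvalue = numeric(), padj = numeric(),
                      significant = logical(), stringsAsFactors = FALSE)
  if (!length(study) || !length(gmt)) return(empty)
  N <- length(universe); n <- length(study)
  rows <- lapply(names(gmt), function(term) {
    members <- intersect(gmt[[term]], universe)
    K <- length(members)
    if (K == 0L) return(NULL)
    k <- length(intersect(members, study))
    p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    desc <- attr(gmt[[term]], "description")
    data.frame(term = term,
               description = if (is.null(desc)) NA_character_ else desc,
               k = k, K = K, n = n, N = N, pvalue = min(max(p, 0), 1),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(empty)
  out$pvalue <- pmax(out$pvalue, .Machine$double.xmin)
  out$padj <- bh_adjust(out$pvalue)
  out$significant <- out$padj < padj_thr
  out <- out[order(out$pvalue, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}
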