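## QTL overlap screening and sum-based GWAS signal enrichment with a
## random-gene-set permutation null.

#' Screen lncRNAs against QTL intervals
#'
#' Retains every (lncRNA, QTL) pair on the same chromosome whose interval
#' gap, `max(0, max(starts) - min(ends))`, is at most `window` bp.
#'
#' @param de_lnc data.frame of lncRNAs with `transcript_id`, `chrom`,
#'   `start`, `end`.
#' @param qtls QTL table from [read_table()] (`chrom`, `start`, `end`,
#'   `trait`, `qtl_id`).
#' @param window maximum gap in bp.
#' @return data.frame `transcript_id`, `qtl_id`, `trait`, `chrom`, `gap`,
#'   one row per retained pair, with attributes `n_rows` and
#'   `n_distinct_lnc`.
#' @export
qtl_overlap <- function(de_lnc, qtls, window = 100000) {
  empty <- data.frame(transcript_id = character(), qtl_id = character(),
                      trait = character(), chrom = character(),
                      gap = numeric(), stringsAsFactors = FALSE)
  if (!nrow(de_lnc) || !nrow(qtls)) {
    attr(empty, "n_rows") <- 0L; attr(empty, "n_distinct_lnc") <- 0L
    return(empty)
  }
  lgr <- GenomicRanges::GRanges(de_lnc$chrom,
                                IRanges::IRanges(de_lnc$start, de_lnc$end))
  qgr <- GenomicRanges::GRanges(as.character(qtls$chrom),
                                IRanges::IRanges(qtls$start, qtls$end))
  hits <- GenomicRanges::findOverlaps(lgr, qgr, maxgap = window - 1,
                                      ignore.strand = TRUE)
  qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
  gap <- .gap_bp(de_lnc$start[qi], de_lnc$end[qi],
                 qtls$start[si], qtls$end[si])
  keep <- gap <= window
  out <- data.frame(transcript_id = de_lnc$transcript_id[qi][keep],
                    qtl_id = as.character(qtls$qtl_id[si][keep]),
                    trait = qtls$trait[si][keep],
                    chrom = de_lnc$chrom[qi][keep],
                    gap = gap[keep],
                    stringsAsFactors = FALSE, row.names = NULL)
  out <- out[order(out$transcript_id, out$qtl_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_rows") <- nrow(out)
  attr(out, "n_distinct_lnc") <- length(unique(out$transcript_id))
  out
}

#' Sum-based GWAS signal enrichment of a gene set
#'
#' Per-SNP signal is the chi-squared(1 df) quantile at `1 - p`. The
#' observed statistic sums the signal over all SNPs lying within `ext` bp
#' of any member gene (closed intervals; a SNP exactly at `gene_end + ext`
#' counts). The null distribution repeats the computation for `n_perm`
#' random gene sets of the same size drawn from `all_genes`, and the
#' empirical p-value is `(1 + #{null >= observed}) / (1 + n_perm)`.
#'
#' The display transform `abs(log10(p + 1))` mirrors the enrichment-degree
#' convention used in heat maps of this analysis (bounded by `log10(2)`);
#' the plain `-log10(p)` is reported alongside.
#'
#' @param gene_set character vector of member gene ids (subset of
#'   `all_genes$gene_id`).
#' @param all_genes data.frame `gene_id`, `chrom`, `start`, `end` for the
#'   whole universe.
#' @param snps GWAS table (`chrom`, `pos`, `pvalue`), already filtered to
#'   one trait.
#' @param ext flanking extension in bp.
#' @param n_perm number of permutations (>= 1).
#' @param seed RNG seed for the permutation draw.
#' @return list of class `GwasEnrichmentResult`: `observed_stat`,
#'   `null_stats`, `emp_p`, `display`, `neglog10_p`, `n_genes`, `n_snps_in_regions`.
#' @export
gwas_sum_enrichment <- function(gene_set, all_genes, snps, ext = 50000,
                                n_perm = 1000, seed = 1) {
  if (n_perm < 1L) stop("n_perm must be >= 1 (null undefined)")
  if (!length(gene_set) || !nrow(snps)) {
    warning("empty gene set or no SNPs; enrichment undefined (emp_p = 1)")
    return(structure(list(observed_stat = 0, null_stats = numeric(),
                          emp_p = 1, display = abs(log10(2)),
                          neglog10_p = 0, n_genes = length(gene_set),
                          n_snps_in_regions = 0L),
                     class = "GwasEnrichmentResult"))
  }
  stopifnot(all(gene_set %in% all_genes$gene_id))
  signal <- qchisq(snps$pvalue, df = 1, lower.tail = FALSE)
  ggr <- GenomicRanges::GRanges(
    all_genes$chrom,
    IRanges::IRanges(pmax(1, all_genes$start - ext), all_genes$end + ext))
  sgr <- GenomicRanges::GRanges(as.character(snps$chrom),
                                IRanges::IRanges(snps$pos, snps$pos))
  hits <- GenomicRanges::findOverlaps(sgr, ggr, ignore.strand = TRUE)
  snp_by_gene <- split(S4Vectors::queryHits(hits),
                       all_genes$gene_id[S4Vectors::subjectHits(hits)])
  set_stat <- function(ids) {
    idx <- unique(unlist(snp_by_gene[ids], use.names = FALSE))
    if (is.null(idx) || !length(idx)) 0 else sum(signal[idx])
  }
  observed <- set_stat(gene_set)
  n_in <- length(unique(unlist(snp_by_gene[gene_set], use.names = FALSE)))
  if (n_in == 0L)
    warning("no SNP within ", ext, " bp of any member gene")
  set.seed(seed)
  k <- length(gene_set)
  null_stats <- vapply(seq_len(n_perm), function(i)
    set_stat(sample(all_genes$gene_id, k)), numeric(1))
  emp_p <- (1 + sum(null_stats >= observed)) / (1 + n_perm)
  structure(list(observed_stat = observed, null_stats = null_stats,
                 emp_p = emp_p,
                 display = abs(log10(emp_p + 1)),
                 neglog10_p = -log10(emp_p),
                 n_genes = k, n_snps_in_regions = n_in),
            class = "GwasEnrichmentResult")
}

#' @export
print.GwasEnrichmentResult <- function(x, ...) {
  cat("GWAS sum enrichment: observed =", format(x$observed_stat),
      "emp_p =", format(x$emp_p), "( n_genes =", x$n_genes, ")\n")
  invisible(x)
}

#' Per-gene significant-SNP counts and Manhattan table
#'
#' Counts, for each member gene, the significant SNPs (p below `sig_thr`)
#' within `ext` bp of the gene span (closed interval: a SNP exactly at the
#' boundary counts), and returns a Manhattan-ready SNP table annotated with
#' the nearest member gene.
#'
#' @param gene_set data.frame `gene_id`, `chrom`, `start`, `end`.
#' @param snps GWAS table (`chrom`, `pos`, `pvalue`).
#' @param ext flanking extension in bp.
#' @param sig_thr significance threshold for a "significant SNP".
#' @return list with `per_gene` (`gene_id`, `n_significant`) and
#'   `manhattan` (`chrom`, `pos`, `neglog10_p`, `significant`,
#'   `nearest_gene`).
#' @export
nearest_snp_report <- function(gene_set, snps, ext = 50000,
                               sig_thr = 5e-8) {
  ggr <- GenomicRanges::GRanges(
    gene_set$chrom,
    IRanges::IRanges(pmax(1, gene_set$start - ext), gene_set$end + ext))
  sgr <- GenomicRanges::GRanges(as.character(snps$chrom),
                                IRanges::IRanges(snps$pos, snps$pos))
  sig <- snps$pvalue < sig_thr
  hits <- GenomicRanges::findOverlaps(sgr, ggr, ignore.strand = TRUE)
  qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
  n_sig <- vapply(seq_len(nrow(gene_set)), function(g)
    sum(sig[qi[si == g]]), integer(1))
  per_gene <- data.frame(gene_id = gene_set$gene_id,
                         n_significant = n_sig,
                         stringsAsFactors = FALSE)
  near <- GenomicRanges::distanceToNearest(
    sgr, GenomicRanges::GRanges(gene_set$chrom,
                                IRanges::IRanges(gene_set$start,
                                                 gene_set$end)),
    ignore.strand = TRUE)
  nearest_gene <- rep(NA_character_, nrow(snps))
  nearest_gene[S4Vectors::queryHits(near)] <-
    gene_set$gene_id[S4Vectors::subjectHits(near)]
  manhattan <- data.frame(chrom = snps$chrom, pos = snps$pos,
                          neglog10_p = -log10(snps$pvalue),
                          significant = sig,
                          nearest_gene = nearest_gene,
                          stringsAsFactors = FALSE)
  list(per_gene = per_gene, manhattan = manhattan)
}
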