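## Target prediction for DE lncRNAs: cis (genomic window), trans (expression
## correlation), a simplified duplex-energy binding screen, SCC regression,
## and assembly of the lncRNA-mRNA-pathway network.

.gap_bp <- function(start_a, end_a, start_b, end_b) {
  pmax(0, pmax(start_a, start_b) - pmin(end_a, end_b))
}

#' Cis target genes within a genomic window
#'
#' Pairs each lncRNA with every protein-coding gene on the same chromosome
#' whose span lies within `window` bp of the lncRNA span. The gap is
#' `max(0, max(starts) - min(ends))` (0 for overlapping intervals); strand
#' is ignored. Pairs with gap <= 1 kb are flagged as `proximal`.
#'
#' @param de_lnc data.frame of lncRNAs with `transcript_id`, `chrom`,
#'   `start`, `end`.
#' @param genes data.frame of genes with `gene_id`, `chrom`, `start`,
#'   `end`.
#' @param window maximum gap in bp.
#' @return data.frame `lnc_id`, `gene_id`, `mode = "cis"`, `distance`,
#'   `proximal`.
#' @export
cis_targets <- function(de_lnc, genes, window = 100000) {
  if (!nrow(de_lnc) || !nrow(genes))
    return(data.frame(lnc_id = character(), gene_id = character(),
                      mode = character(), distance = numeric(),
                      proximal = logical(), stringsAsFactors = FALSE))
  lgr <- GenomicRanges::GRanges(de_lnc$chrom,
                                IRanges::IRanges(de_lnc$start, de_lnc$end))
  ggr <- GenomicRanges::GRanges(genes$chrom,
                                IRanges::IRanges(genes$start, genes$end))
  # gap <= window corresponds to maxgap = window - 1 in GRanges semantics
  # (its gap counts bases strictly between the intervals)
  hits <- GenomicRanges::findOverlaps(lgr, ggr, maxgap = window - 1,
                                      ignore.strand = TRUE)
  qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
  distance <- .gap_bp(de_lnc$start[qi], de_lnc$end[qi],
                      genes$start[si], genes$end[si])
  keep <- distance <= window
  out <- data.frame(lnc_id = de_lnc$transcript_id[qi][keep],
                    gene_id = genes$gene_id[si][keep],
                    mode = "cis",
                    distance = distance[keep],
                    proximal = distance[keep] <= 1000,
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(out$lnc_id, out$gene_id), , drop = FALSE]
}

#' Trans target genes by expression correlation
#'
#' Pearson correlation between DE lncRNAs and DE mRNAs on the normalized
#' log expression of the given comparison's samples only. A pair is kept
#' when `|R| > r_thr` and the two-sided t-transform p-value is below
#' `p_thr`. Zero-variance features are skipped with a log entry.
#'
#' @param norm_expr normalized log expression, features in rows.
#' @param de_lnc_ids,de_mrna_ids feature ids to correlate.
#' @param samples column names (or indices) of the comparison's samples;
#'   at least 3.
#' @param r_thr,p_thr retention thresholds.
#' @return data.frame `lnc_id`, `gene_id`, `mode = "trans"`, `pcc`,
#'   `pcc_p`.
#' @export
trans_targets <- function(norm_expr, de_lnc_ids, de_mrna_ids, samples,
                          r_thr = 0.95, p_thr = 0.05) {
  x <- norm_expr[, samples, drop = FALSE]
  n <- ncol(x)
  if (n < 3L) stop("need >= 3 samples for trans-target correlation")
  empty <- data.frame(lnc_id = character(), gene_id = character(),
                      mode = character(), pcc = numeric(),
                      pcc_p = numeric(), stringsAsFactors = FALSE)
  lnc_ids <- intersect(de_lnc_ids, rownames(x))
  mrna_ids <- intersect(de_mrna_ids, rownames(x))
  if (!length(lnc_ids) || !length(mrna_ids)) return(empty)
  lv <- apply(x[lnc_ids, , drop = FALSE], 1L, sd)
  mv <- apply(x[mrna_ids, , drop = FALSE], 1L, sd)
  if (any(lv == 0) || any(mv == 0))
    .log("skipping %d zero-variance feature(s) in trans-target screen",
         sum(lv == 0) + sum(mv == 0))
  lnc_ids <- lnc_ids[lv > 0]; mrna_ids <- mrna_ids[mv > 0]
  if (!length(lnc_ids) || !length(mrna_ids)) return(empty)
  r <- cor(t(x[lnc_ids, , drop = FALSE]), t(x[mrna_ids, , drop = FALSE]))
  r <- pmin(pmax(r, -1), 1)
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, 1e-12))
  p <- 2 * pt(-abs(tstat), df = n - 2)
  keep <- which(abs(r) > r_thr & p < p_thr, arr.ind = TRUE)
  if (!nrow(keep)) return(empty)
  out <- data.frame(lnc_id = lnc_ids[keep[, 1L]],
                    gene_id = mrna_ids[keep[, 2L]],
                    mode = "trans",
                    pcc = r[keep], pcc_p = p[keep],
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(out$lnc_id, out$gene_id), , drop = FALSE]
}

# RNA nearest-neighbor stack free energies (kcal/mol) for Watson-Crick
# duplexes, keyed by the 5'->3' dinucleotide on one strand.
.stack_energy <- c(
  AA = -0.93, UU = -0.93, AU = -1.10, UA = -1.33,
  CU = -2.08, AG = -2.08, CA = -2.11, UG = -2.11,
  GU = -2.24, AC = -2.24, GA = -2.35, UC = -2.35,
  CG = -2.36, GG = -3.26, CC = -3.26, GC = -3.42)

#' Simplified lncRNA-mRNA binding screen by normalized duplex energy
#'
#' A deliberately simplified RNA-RNA interaction screen: the lncRNA is slid
#' along the reverse complement of the target at every offset; at each
#' offset the best contiguous complementary stretch is scored with the
#' nearest-neighbor stacking table (no loops, bulges or dangling ends), and
#' the minimum free energy over all offsets is normalized by the length of
#' the shorter sequence. `ndg < ndg_thr` (strict) calls the pair bound.
#' The scale mimics length-normalized duplex energies but is not
#' thermodynamically accurate.
#'
#' @param lnc_seq,target_seq DNA/RNA sequences (character), >= 20 nt.
#' @param ndg_thr binding threshold on the normalized free energy.
#' @return list with `ndg` (dimensionless, <= 0) and `bound` (logical).
#' @export
ndg_screen <- function(lnc_seq, target_seq, ndg_thr = -0.08) {
  x <- toupper(chartr("T", "U", as.character(lnc_seq)))
  y <- toupper(chartr("T", "U", as.character(target_seq)))
  if (nchar(x) < 20L || nchar(y) < 20L)
    stop("sequences must be >= 20 nt for the binding screen")
  if (grepl("[^ACGU]", x) || grepl("[^ACGU]", y))
    stop("sequences must be ACGT/ACGU")
  xc <- strsplit(x, "", fixed = TRUE)[[1L]]
  # reverse complement of the target, so complementarity becomes equality
  yc <- rev(strsplit(chartr("ACGU", "UGCA", y), "", fixed = TRUE)[[1L]])
  nx <- length(xc); ny <- length(yc)
  dg_min <- 0
  for (off in seq.int(-(ny - 2L), nx - 2L)) {
    i1 <- max(1L, 1L + off); i2 <- min(nx, ny + off)
    if (i2 - i1 < 1L) next
    xs <- xc[i1:i2]
    ys <- yc[(i1 - off):(i2 - off)]
    m <- xs == ys
    if (sum(m) < 2L) next
    stack_ok <- m[-length(m)] & m[-1L]
    if (!any(stack_ok)) next
    e <- ifelse(stack_ok,
                unname(.stack_energy[paste0(xs[-length(xs)], xs[-1L])]), 0)
    # best (most negative) contiguous run of stacks, via run-length sums
    neg <- e < 0
    r <- rle(neg)
    if (!any(r$values)) next
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    cs <- c(0, cumsum(e))
    run_sums <- cs[ends[r$values] + 1L] - cs[starts[r$values]]
    best <- min(run_sums)
    if (best < dg_min) dg_min <- best
  }
  ndg <- dg_min / min(nx, ny)
  list(ndg = ndg, bound = ndg < ndg_thr)
}

#' Regression of target-gene expression on somatic cell count
#'
#' Ordinary least squares of a gene's normalized expression on per-sample
#' SCC, with the two-sided p-value on the slope.
#'
#' @param expr_gene numeric vector of expression values, one per sample.
#' @param scc numeric vector of somatic cell counts (x1000 cells/mL).
#' @return list `slope`, `r`, `pvalue`, `significant` (p < 0.05).
#' @export
scc_regression <- function(expr_gene, scc) {
  stopifnot(length(expr_gene) == length(scc))
  if (length(scc) < 3L) stop("need >= 3 samples with SCC")
  if (sd(scc) == 0) stop("SCC is constant; regression undefined")
  fit <- lm(expr_gene ~ scc)
  # a perfect linear relation triggers a benign "perfect fit" warning
  sm <- suppressWarnings(summary(fit))$coefficients
  p <- if (nrow(sm) >= 2L) sm["scc", "Pr(>|t|)"] else NA_real_
  list(slope = unname(coef(fit)[["scc"]]),
       r = cor(expr_gene, scc),
       pvalue = unname(p),
       significant = is.finite(p) && p < 0.05)
}

#' Merge cis and trans evidence into unique target pairs
#'
#' @param cis,trans data.frames from [cis_targets()] and [trans_targets()].
#' @return one row per (lnc, gene) pair with `mode` in cis/trans/both and
#'   both evidence fields populated where available.
#' @export
merge_target_pairs <- function(cis, trans) {
  key_c <- paste(cis$lnc_id, cis$gene_id)
  key_t <- paste(trans$lnc_id, trans$gene_id)
  all_keys <- union(key_c, key_t)
  ic <- match(all_keys, key_c); it <- match(all_keys, key_t)
  out <- data.frame(
    lnc_id = ifelse(is.na(ic), trans$lnc_id[it], cis$lnc_id[ic]),
    gene_id = ifelse(is.na(ic), trans$gene_id[it], cis$gene_id[ic]),
    mode = ifelse(!is.na(ic) & !is.na(it), "both",
                  ifelse(is.na(it), "cis", "trans")),
    distance = ifelse(is.na(ic), NA_real_, cis$distance[ic]),
    pcc = ifelse(is.na(it), NA_real_, trans$pcc[it]),
    pcc_p = ifelse(is.na(it), NA_real_, trans$pcc_p[it]),
    stringsAsFactors = FALSE, row.names = NULL)
  out[order(out$lnc_id, out$gene_id), , drop = FALSE]
}

#' Assemble the lncRNA-mRNA-pathway network
#'
#' Builds a tripartite edge list: one edge per predicted lncRNA-gene pair
#' and one edge per (gene, enriched pathway) membership. Node attributes
#' carry the node type and, for genes, the DE direction. Output ordering is
#' deterministic.
#'
#' @param target_pairs data.frame with `lnc_id`, `gene_id` (e.g. from
#'   [merge_target_pairs()]).
#' @param de_status named character vector feature -> status (up/down/ns).
#' @param pathway_hits data.frame with `term` and `gene_id` columns listing
#'   enriched-pathway memberships of target genes (may be empty).
#' @return list with `edges` (`from`, `to`, `type`) and `nodes`
#'   (`id`, `type`, `de_status`).
#' @export
build_network <- function(target_pairs, de_status = character(),
                          pathway_hits = NULL) {
  e1 <- data.frame(from = target_pairs$lnc_id, to = target_pairs$gene_id,
                   type = rep("lnc-gene", nrow(target_pairs)),
                   stringsAsFactors = FALSE)
  e2 <- NULL
  if (!is.null(pathway_hits) && nrow(pathway_hits)) {
    use <- pathway_hits$gene_id %in% target_pairs$gene_id
    e2 <- data.frame(from = pathway_hits$gene_id[use],
                     to = pathway_hits$term[use],
                     type = "gene-pathway", stringsAsFactors = FALSE)
  }
  edges <- rbind(e1, e2)
  edges <- unique(edges[order(edges$type, edges$from, edges$to), ,
                        drop = FALSE])
  rownames(edges) <- NULL
  nodes <- data.frame(
    id = c(unique(target_pairs$lnc_id), unique(target_pairs$gene_id),
           if (!is.null(e2)) unique(e2$to)),
    type = c(rep("lncRNA", length(unique(target_pairs$lnc_id))),
             rep("gene", length(unique(target_pairs$gene_id))),
             rep("pathway", if (!is.null(e2)) length(unique(e2$to)) else 0L)),
    stringsAsFactors = FALSE)
  nodes$de_status <- ifelse(nodes$id %in% names(de_status),
                            unname(de_status[nodes$id]), NA_character_)
  nodes <- nodes[order(nodes$type, nodes$id), , drop = FALSE]
  rownames(nodes) <- NULL
  list(edges = edges, nodes = nodes)
}
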