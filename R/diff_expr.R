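## Negative-binomial differential expression: median-of-ratios size factors,
## log-normalized expression, per-feature NB Wald test with moment-based
## dispersion shrunk toward the across-feature trend, and threshold calling.
## This is a compact, documented re-implementation of the standard workflow,
## not a clone of any particular package; exact numerical agreement with
## other NB engines is a non-goal.

#' Independent filtering of low-count features
#'
#' Keeps features with at least `min_samples` samples at or above
#' `min_count` reads.
#'
#' @param counts integer matrix, features in rows.
#' @param min_count,min_samples filter thresholds.
#' @return the filtered counts matrix.
#' @export
prefilter_counts <- function(counts, min_count = 10, min_samples = 2) {
  keep <- rowSums(counts >= min_count) >= min_samples
  counts[keep, , drop = FALSE]
}

#' Median-of-ratios size factors
#'
#' For each sample, the size factor is the median across features of the
#' ratio of that sample's count to the feature's geometric mean, computed
#' over features with all-positive counts. When no such feature exists the
#' function falls back to total-count ratios with a warning. Factors are
#' rescaled to have geometric mean 1.
#'
#' @param counts integer matrix, features in rows.
#' @return named numeric vector of positive per-sample factors.
#' @export
size_factors <- function(counts) {
  allpos <- rowSums(counts == 0) == 0L
  if (!any(allpos)) {
    warning("no feature with all-positive counts; ",
            "falling back to total-count size factors")
    sf <- colSums(counts)
    sf <- sf / exp(mean(log(sf)))
    return(sf)
  }
  m <- counts[allpos, , drop = FALSE]
  loggeo <- rowMeans(log(m))
  sf <- apply(m, 2L, function(col) exp(median(log(col) - loggeo)))
  sf / exp(mean(log(sf)))
}

#' Log2 normalized expression
#'
#' `log2(count / size_factor + 1)`, elementwise. A simple variance-taming
#' transform used downstream for correlation and module analysis.
#'
#' @param counts integer matrix, features in rows.
#' @param factors size factors from [size_factors()].
#' @return numeric matrix of the same dimension.
#' @export
normalized_log <- function(counts, factors = size_factors(counts)) {
  stopifnot(length(factors) == ncol(counts))
  log2(sweep(counts, 2L, factors, "/") + 1)
}

#' Per-feature negative-binomial Wald test
#'
#' For each feature, group means are estimated on size-factor-normalized
#' counts. Per-feature NB dispersion is estimated by the method of moments
#' within groups and shrunk 50/50 toward the across-feature trend (the mean
#' moment estimate). The Wald statistic is the log2 fold change (treatment
#' over control, 0.5 pseudocount) divided by its delta-method standard
#' error; two-sided p-values use the standard normal reference (the
#' blending of the model-based variance with the across-feature trend keeps
#' the statistic close to normal even at small group sizes). BH-adjusted
#' p-values are computed across all tested features.
#'
#' @param counts prefiltered integer matrix, features in rows.
#' @param groups character vector assigning each column to a group.
#' @param comparison two group labels `c(treatment, control)`, or a string
#'   `"AvsB"`.
#' @param factors size factors (defaults to [size_factors()] of `counts`).
#' @return data.frame with `feature_id`, `comparison`, `baseMean`, `log2fc`,
#'   `pvalue`, `padj`.
#' @export
nb_wald_test <- function(counts, groups, comparison,
                         factors = size_factors(counts)) {
  if (length(comparison) == 1L)
    comparison <- strsplit(comparison, "vs", fixed = TRUE)[[1L]]
  stopifnot(length(comparison) == 2L)
  trt <- comparison[[1L]]; ctl <- comparison[[2L]]
  it <- which(groups == trt); ic <- which(groups == ctl)
  if (length(it) < 2L || length(ic) < 2L)
    stop("need >= 2 samples per group for ", trt, " vs ", ctl)
  q <- sweep(counts, 2L, factors, "/")
  qt_ <- q[, it, drop = FALSE]; qc_ <- q[, ic, drop = FALSE]
  nt <- length(it); nc <- length(ic)
  mu_t <- rowMeans(qt_); mu_c <- rowMeans(qc_)
  v_t <- apply(qt_, 1L, var); v_c <- apply(qc_, 1L, var)

  # moment estimate of NB dispersion alpha from var = mu + alpha mu^2,
  # pooled across the two groups, floored at ~Poisson
  mom <- function(v, mu) ifelse(mu > 0, (v - mu) / mu^2, NA_real_)
  a_t <- mom(v_t, mu_t); a_c <- mom(v_c, mu_c)
  w_t <- (nt - 1) / (nt + nc - 2); w_c <- 1 - w_t
  a_feat <- ifelse(is.na(a_t) & is.na(a_c), NA_real_,
                   ifelse(is.na(a_t), a_c,
                          ifelse(is.na(a_c), a_t,
                                 w_t * a_t + w_c * a_c)))
  # the trend averages the raw (possibly negative) moment estimates so that
  # sampling noise cancels instead of accumulating through a floor
  trend <- mean(a_feat, na.rm = TRUE)
  if (!is.finite(trend)) trend <- 0.1
  alpha <- 0.5 * a_feat + 0.5 * trend
  alpha[is.na(alpha)] <- trend
  alpha <- pmax(alpha, 0)

  pseud <- 0.5
  log2fc <- log2((mu_t + pseud) / (mu_c + pseud))
  var_mu_t <- (mu_t + alpha * mu_t^2) / nt
  var_mu_c <- (mu_c + alpha * mu_c^2) / nc
  se <- sqrt(var_mu_t / (mu_t + pseud)^2 + var_mu_c / (mu_c + pseud)^2) /
    log(2)
  z <- ifelse(se > 0, log2fc / se, 0)
  pvalue <- 2 * pnorm(-abs(z))
  # all-zero feature in both groups carries no evidence
  pvalue[mu_t == 0 & mu_c == 0] <- 1
  pvalue <- pmin(pmax(pvalue, .Machine$double.xmin), 1)
  data.frame(feature_id = rownames(counts),
             comparison = paste0(trt, "vs", ctl),
             baseMean = (mu_t * nt + mu_c * nc) / (nt + nc),
             log2fc = unname(log2fc),
             pvalue = unname(pvalue),
             padj = unname(bh_adjust(pvalue)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up FDR adjustment (delegates to [stats::p.adjust()] with
#' `method = "BH"`).
#'
#' @param pvalues numeric vector of p-values in (0, 1].
#' @return adjusted p-values, never below the input and capped at 1.
#' @export
bh_adjust <- function(pvalues) {
  stopifnot(all(pvalues > 0 & pvalues <= 1))
  pmax(p.adjust(pvalues, method = "BH"), pvalues)
}

#' Threshold-based differential expression calls
#'
#' Labels each feature `up` when `log2fc > lfc_thr` and `pvalue < p_thr`,
#' `down` when `log2fc < -lfc_thr` and `pvalue < p_thr`, otherwise `ns`.
#' Both inequalities are strict. Calling uses the raw p-value (adjusted
#' p-values are reported alongside but not used for the call; see the
#' methods vignette for the rationale).
#'
#' @param results data.frame from [nb_wald_test()] (needs `log2fc`,
#'   `pvalue`).
#' @param lfc_thr,p_thr calling thresholds.
#' @return the input with a `status` column added.
#' @export
call_de <- function(results, lfc_thr = 1, p_thr = 0.05) {
  status <- rep("ns", nrow(results))
  sig <- results$pvalue < p_thr
  status[sig & results$log2fc > lfc_thr] <- "up"
  status[sig & results$log2fc < -lfc_thr] <- "down"
  results$status <- status
  results
}

#' Features differentially expressed in two comparisons
#'
#' Intersects the DE feature sets of two comparisons and annotates sign
#' concordance. Commutative and idempotent on the feature sets.
#'
#' @param resA,resB data.frames from [call_de()] for the two comparisons.
#' @return data.frame `feature_id`, `status_A`, `status_B`, `concordant`.
#' @export
shared_de <- function(resA, resB) {
  deA <- resA[resA$status != "ns", c("feature_id", "status")]
  deB <- resB[resB$status != "ns", c("feature_id", "status")]
  ids <- intersect(deA$feature_id, deB$feature_id)
  sa <- deA$status[match(ids, deA$feature_id)]
  sb <- deB$status[match(ids, deB$feature_id)]
  data.frame(feature_id = ids, status_A = sa, status_B = sb,
             concordant = sa == sb, stringsAsFactors = FALSE,
             row.names = NULL)
}
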