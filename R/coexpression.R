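## Weighted co-expression analysis: soft threshold chosen by scale-free
## topology fit, topological-overlap similarity, average-linkage modules via
## a modularity-guided height cut, module eigengenes, and eigengene-trait
## correlation. Unsigned network (|cor|^beta) throughout.

.module_colors <- c("turquoise", "blue", "brown", "yellow", "green", "red",
                    "black", "pink", "magenta", "purple", "greenyellow",
                    "tan", "salmon", "cyan", "midnightblue", "lightcyan",
                    "grey60", "lightgreen", "lightyellow", "royalblue")

.adjacency <- function(expr, beta) {
  a <- abs(cor(t(expr)))^beta
  diag(a) <- 0
  a
}

.scale_free_r2 <- function(k, nbins = 10) {
  k <- k[k > 0]
  if (length(unique(round(k, 10))) < 3L) return(NA_real_)
  cuts <- cut(k, breaks = nbins)
  dk <- tapply(k, cuts, mean)
  pk <- tapply(k, cuts, length) / length(k)
  ok <- !is.na(dk) & dk > 0 & !is.na(pk) & pk > 0
  if (sum(ok) < 3L) return(NA_real_)
  fit <- lm(log10(pk[ok]) ~ log10(dk[ok]))
  summary(fit)$r.squared
}

#' Choose the soft-threshold power by scale-free topology fit
#'
#' For each candidate power `beta`, builds the unsigned adjacency
#' `|cor|^beta`, computes the connectivity distribution and the R-squared of
#' the log-log regression of frequency on connectivity (the scale-free
#' topology fit). The chosen `beta` is the smallest candidate whose fit
#' exceeds `r2_target`; if none qualifies the `beta` with the maximal fit is
#' returned with a warning.
#'
#' @param expr normalized expression matrix, features in rows, >= 4 samples.
#' @param betas candidate integer powers.
#' @param r2_target target scale-free fit R-squared.
#' @return list of class `SoftThresholdResult`: `beta`, `r2`, and
#'   `candidates` (data.frame of beta, r2, mean connectivity).
#' @export
pick_soft_threshold <- function(expr, betas = 1:20, r2_target = 0.9) {
  if (ncol(expr) < 4L) stop("need >= 4 samples for co-expression analysis")
  absc <- abs(cor(t(expr)))
  diag(absc) <- 0
  cand <- data.frame(beta = betas, r2 = NA_real_, mean_k = NA_real_)
  for (i in seq_along(betas)) {
    a <- absc^betas[i]
    k <- rowSums(a)
    cand$mean_k[i] <- mean(k)
    cand$r2[i] <- .scale_free_r2(k)
  }
  if (all(is.na(cand$r2))) {
    warning("scale-free fit undefined (degenerate connectivity); ",
            "using smallest beta")
    beta <- betas[1L]; r2 <- NA_real_
  } else if (any(cand$r2 > r2_target, na.rm = TRUE)) {
    i <- which(cand$r2 > r2_target)[1L]
    beta <- cand$beta[i]; r2 <- cand$r2[i]
  } else {
    i <- which.max(cand$r2)
    beta <- cand$beta[i]; r2 <- cand$r2[i]
    warning("no candidate power reached R2 > ", r2_target,
            "; using beta = ", beta, " (max R2 = ", round(r2, 3), ")")
  }
  structure(list(beta = beta, r2 = r2, candidates = cand),
            class = "SoftThresholdResult")
}

#' Topological overlap matrix
#'
#' `TOM_ij = (L_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' `L = A %*% A` (adjacency with zero diagonal) and unit diagonal.
#'
#' @param adjacency square symmetric adjacency matrix, zero diagonal.
#' @return TOM similarity matrix in \[0, 1\] with unit diagonal.
#' @export
tom_similarity <- function(adjacency) {
  k <- rowSums(adjacency)
  l <- adjacency %*% adjacency
  kmin <- outer(k, k, pmin)
  tom <- (l + adjacency) / (kmin + 1 - adjacency)
  diag(tom) <- 1
  tom
}

#' Detect co-expression modules
#'
#' Builds the unsigned adjacency at the chosen power, converts it to
#' topological-overlap dissimilarity, clusters by average linkage, and cuts
#' the tree at the height (scanned over the merge-height range) that
#' maximizes weighted modularity of the induced partition on the adjacency
#' graph. Clusters below `min_module_size` fall into the unassigned module
#' `"grey"`. Modules are labeled by size with conventional color names and
#' summarized by their eigengene (first principal component of standardized
#' member expression, oriented so the mean member correlation is positive).
#'
#' @param expr normalized expression matrix, features in rows.
#' @param beta soft-threshold power (see [pick_soft_threshold()]).
#' @param min_module_size smallest allowed module.
#' @param min_pc1_share module cohesion floor: candidate modules whose
#'   eigengene (first PC of standardized member expression) explains less
#'   than this share of member variance are dissolved into `"grey"`.
#'   Guards against loose clusters of mutually uncorrelated genes.
#' @return list of class `coexpression_modules`: `assignment` (data.frame
#'   gene/module), `members` (list module -> gene ids), `eigengenes`
#'   (samples x modules matrix), `beta`, `tree` (hclust), `cut_height`.
#' @export
detect_modules <- function(expr, beta, min_module_size = 30,
                           min_pc1_share = 0.3) {
  a <- .adjacency(expr, beta)
  tom <- tom_similarity(a)
  d <- stats::as.dist(1 - tom)
  tree <- hclust(d, method = "average")
  heights <- quantile(tree$height, probs = seq(0.1, 0.98, by = 0.04),
                      names = FALSE)
  g <- igraph::graph_from_adjacency_matrix(a, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  best <- list(q = -Inf, labels = NULL, h = NA_real_)
  for (h in unique(heights)) {
    lab <- cutree(tree, h = h)
    tab <- table(lab)
    small <- as.integer(names(tab)[tab < min_module_size])
    lab_mod <- lab
    lab_mod[lab %in% small] <- 0L
    if (!any(lab_mod > 0L)) next
    # modularity with unassigned genes as singleton communities
    memb <- lab_mod
    nsing <- sum(memb == 0L)
    if (nsing) memb[memb == 0L] <- max(memb) + seq_len(nsing)
    q <- igraph::modularity(g, membership = memb,
                            weights = igraph::E(g)$weight)
    if (q > best$q) best <- list(q = q, labels = lab_mod, h = h)
  }
  genes <- rownames(expr)
  if (is.null(best$labels)) {
    assignment <- data.frame(gene = genes, module = "grey",
                             stringsAsFactors = FALSE)
    return(structure(list(assignment = assignment, members = list(),
                          eigengenes = NULL, beta = beta, tree = tree,
                          cut_height = NA_real_),
                     class = "coexpression_modules"))
  }
  lab <- best$labels
  # cohesion floor: dissolve candidate clusters whose eigengene explains
  # little member variance
  for (cl in unique(lab[lab > 0L])) {
    gs <- which(lab == cl)
    x <- t(scale(t(expr[gs, , drop = FALSE])))
    x[!is.finite(x)] <- 0
    ev <- prcomp(t(x), center = FALSE)$sdev^2
    if (ev[1L] / sum(ev) < min_pc1_share) lab[gs] <- 0L
  }
  if (!any(lab > 0L)) {
    assignment <- data.frame(gene = genes, module = "grey",
                             stringsAsFactors = FALSE)
    return(structure(list(assignment = assignment, members = list(),
                          eigengenes = NULL, beta = beta, tree = tree,
                          cut_height = best$h),
                     class = "coexpression_modules"))
  }
  sizes <- sort(table(lab[lab > 0L]), decreasing = TRUE)
  ids <- as.integer(names(sizes))
  color <- setNames(c(.module_colors, paste0("module", seq_along(ids)))
                    [seq_along(ids)], ids)
  module <- ifelse(lab > 0L, color[as.character(lab)], "grey")
  assignment <- data.frame(gene = genes, module = unname(module),
                           stringsAsFactors = FALSE)
  members <- split(assignment$gene, assignment$module)
  members <- members[setdiff(names(members), "grey")]
  me <- vapply(members, function(gs) module_eigengene(expr[gs, , drop = FALSE]),
               numeric(ncol(expr)))
  rownames(me) <- colnames(expr)
  # kME refinement (standard membership-by-eigengene-correlation pass):
  # prune members weakly correlated with their module eigengene, then
  # rescue unassigned genes tightly correlated with one
  kme_all <- function(me) {
    k <- suppressWarnings(abs(cor(t(expr), me)))
    k[!is.finite(k)] <- 0
    rownames(k) <- rownames(expr)
    k
  }
  k <- kme_all(me)
  for (mod in colnames(me)) {
    mem <- members[[mod]]
    weak <- mem[k[mem, mod] < 0.5]
    if (length(weak))
      assignment$module[match(weak, assignment$gene)] <- "grey"
  }
  members <- split(assignment$gene, assignment$module)
  members <- members[names(members) != "grey"]
  members <- members[vapply(members, length, integer(1)) >=
                       min_module_size]
  assignment$module[!(assignment$gene %in% unlist(members))] <- "grey"
  if (!length(members)) {
    return(structure(list(assignment = assignment, members = list(),
                          eigengenes = NULL, beta = beta, tree = tree,
                          cut_height = best$h),
                     class = "coexpression_modules"))
  }
  me <- vapply(members, function(gs) module_eigengene(expr[gs, , drop = FALSE]),
               numeric(ncol(expr)))
  rownames(me) <- colnames(expr)
  grey_genes <- assignment$gene[assignment$module == "grey"]
  if (length(grey_genes)) {
    k <- kme_all(me)[grey_genes, , drop = FALSE]
    pick <- max.col(k, ties.method = "first")
    best_mod <- colnames(k)[pick]
    best_val <- k[cbind(seq_along(grey_genes), pick)]
    rescue <- best_val >= 0.7
    if (any(rescue)) {
      assignment$module[match(grey_genes[rescue], assignment$gene)] <-
        best_mod[rescue]
      members <- split(assignment$gene, assignment$module)
      members <- members[names(members) != "grey"]
      me <- vapply(members,
                   function(gs) module_eigengene(expr[gs, , drop = FALSE]),
                   numeric(ncol(expr)))
      rownames(me) <- colnames(expr)
    }
  }
  structure(list(assignment = assignment, members = members,
                 eigengenes = me, beta = beta, tree = tree,
                 cut_height = best$h),
            class = "coexpression_modules")
}

#' Module eigengene
#'
#' First principal component of the standardized member expression, as a
#' per-sample score, sign-oriented so that the mean correlation between the
#' eigengene and member profiles is positive.
#'
#' @param expr_members expression matrix of module members (genes x
#'   samples).
#' @return numeric vector, one score per sample.
#' @export
module_eigengene <- function(expr_members) {
  x <- t(scale(t(expr_members)))        # standardize genes across samples
  x[!is.finite(x)] <- 0                  # constant gene guard
  pc <- prcomp(t(x), center = FALSE, scale. = FALSE)
  me <- pc$x[, 1L]
  cors <- suppressWarnings(cor(me, t(x)))
  if (mean(cors, na.rm = TRUE) < 0) me <- -me
  unname(me)
}

#' Correlate module eigengenes with sample traits
#'
#' Pearson correlation of each module eigengene with each trait column,
#' with p-values from the t transform on `n - 2` degrees of freedom.
#' Constant traits give `NA` correlation.
#'
#' @param modules `coexpression_modules` from [detect_modules()].
#' @param sample_traits data.frame/matrix of numeric traits, one row per
#'   sample in the column order of the expression matrix (e.g. one-hot
#'   group indicators and SCC).
#' @param p_thr significance flag threshold.
#' @return data.frame `module`, `trait`, `r`, `pvalue`, `significant`.
#' @export
module_trait <- function(modules, sample_traits, p_thr = 0.05) {
  me <- modules$eigengenes
  if (is.null(me) || !ncol(me))
    return(data.frame(module = character(), trait = character(),
                      r = numeric(), pvalue = numeric(),
                      significant = logical(), stringsAsFactors = FALSE))
  traits <- as.data.frame(sample_traits)
  stopifnot(nrow(traits) == nrow(me))
  n <- nrow(me)
  out <- expand.grid(module = colnames(me), trait = names(traits),
                     stringsAsFactors = FALSE)
  out$r <- NA_real_; out$pvalue <- NA_real_
  for (i in seq_len(nrow(out))) {
    tv <- traits[[out$trait[i]]]
    if (sd(tv) == 0 || !is.numeric(tv)) next
    r <- cor(me[, out$module[i]], tv)
    tstat <- r * sqrt((n - 2) / max(1 - r^2, 1e-12))
    out$r[i] <- r
    out$pvalue[i] <- 2 * pt(-abs(tstat), df = n - 2)
  }
  out$significant <- !is.na(out$pvalue) & out$pvalue < p_thr
  out
}
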