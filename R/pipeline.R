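## End-to-end orchestration: identify -> DE -> modules -> targets ->
## integration -> ORA, from a single configuration list. Each stage consumes
## only prior stage outputs; the run is a DAG and is reproducible from
## (config, seed).

#' Default pipeline configuration
#'
#' Returns the full configuration list with every stage threshold at its
#' documented default. Input paths are `NULL` and must be filled in.
#'
#' @return named list of configuration entries.
#' @export
default_config <- function() {
  list(
    assembly_gtf = NULL, reference_gtf = NULL, fasta = NULL,
    counts = NULL, samples = NULL, qtl = NULL, gwas = NULL, gmt = NULL,
    outdir = NULL, seed = 1,
    min_exons = 2, min_length = 200, min_count = 1,
    prefilter_min_count = 10, prefilter_min_samples = 2,
    lfc_thr = 1, p_thr = 0.05,
    r2_target = 0.9, min_module_size = 30, max_module_genes = 500,
    window = 1e5, r_thr = 0.95, ndg_thr = -0.08, ndg_max_pairs = 20,
    ext = 5e4, n_perm = 1000, sig_snp_thr = 5e-8,
    ora_padj_thr = 0.05,
    stages = c("identify", "de", "modules", "targets", "integrate", "ora"))
}

.stage_enabled <- function(config, stage) stage %in% config$stages

#' Run the full pipeline from one configuration
#'
#' Stages run in order: lncRNA identification, differential expression
#' (SF vs. SC and HF vs. HC, mRNAs and lncRNAs), co-expression modules on
#' the protein-coding genes, cis/trans target prediction for the DE
#' lncRNAs, QTL overlap and GWAS enrichment, and over-representation
#' analysis of the DE gene sets when a GMT is supplied. Outputs are written
#' with [write_results()] when `config$outdir` is set.
#'
#' @param config configuration list, see [default_config()]. Required input
#'   paths must exist for the enabled stages.
#' @return list with per-stage results and the output manifest.
#' @export
run_pipeline <- function(config) {
  cfg <- utils::modifyList(default_config(), config)
  need <- c(assembly_gtf = "identify", reference_gtf = "identify",
            fasta = "identify", counts = "identify", samples = "de")
  for (inp in names(need)) {
    if (.stage_enabled(cfg, need[[inp]]) && is.null(cfg[[inp]]))
      stop("configuration error: input '", inp, "' required for stage '",
           need[[inp]], "'")
  }
  if (.stage_enabled(cfg, "integrate") &&
      (is.null(cfg$qtl) || is.null(cfg$gwas)))
    stop("configuration error: qtl and gwas inputs required for stage ",
         "'integrate'")
  set.seed(cfg$seed)

  assembly <- read_gtf(cfg$assembly_gtf, "assembly")
  reference <- read_gtf(cfg$reference_gtf, "reference")
  sequences <- {
    ss <- Biostrings::readDNAStringSet(cfg$fasta)
    setNames(as.character(ss), sub("\\s.*$", "", names(ss)))
  }
  counts <- read_table(cfg$counts, "counts")
  samples <- read_table(cfg$samples, "samples")

  res <- list(config = cfg)
  tables <- list()

  ## identification
  ident <- identify_lncrnas(assembly, reference, sequences, counts,
                            min_exons = cfg$min_exons,
                            min_length = cfg$min_length,
                            min_count = cfg$min_count)
  res$catalog <- ident$catalog
  res$scores <- ident$scores
  tables$lncrna_catalog <- ident$catalog[, c("transcript_id", "class_code",
                                             "category", "novel", "chrom",
                                             "start", "end", "length",
                                             "exon_count")]
  tables$coding_potential_scores <- ident$scores
  res$report <- feature_report(ident$catalog)

  ## expressed universe & normalized expression
  ref_pc <- reference$transcripts$transcript_id[
    reference$transcripts$biotype %in% "protein_coding"]
  mrna_ids <- assembly$transcripts$transcript_id[
    assembly$transcripts$class_code %in% "=" &
      assembly$transcripts$cmp_ref %in% ref_pc]
  filt <- prefilter_counts(counts, cfg$prefilter_min_count,
                           cfg$prefilter_min_samples)
  sf <- size_factors(filt)
  norm <- normalized_log(filt, sf)
  res$size_factors <- sf

  ## differential expression
  de <- list()
  if (.stage_enabled(cfg, "de")) {
    groups <- samples$group[match(colnames(filt), samples$sample_id)]
    for (cmp in c("SFvsSC", "HFvsHC")) {
      r <- nb_wald_test(filt, groups, cmp, factors = sf)
      r <- call_de(r, cfg$lfc_thr, cfg$p_thr)
      r$feature_type <- ifelse(r$feature_id %in% mrna_ids, "mRNA",
                               ifelse(r$feature_id %in%
                                        res$catalog$transcript_id,
                                      "lncRNA", "other"))
      de[[cmp]] <- r
      tables[[paste0("de_", cmp)]] <- r
    }
    res$de <- de
    res$shared_mrna <- shared_de(
      de$SFvsSC[de$SFvsSC$feature_type == "mRNA", ],
      de$HFvsHC[de$HFvsHC$feature_type == "mRNA", ])
    res$shared_lnc <- shared_de(
      de$SFvsSC[de$SFvsSC$feature_type == "lncRNA", ],
      de$HFvsHC[de$HFvsHC$feature_type == "lncRNA", ])
    tables$shared_de_mrna <- res$shared_mrna
    tables$shared_de_lncrna <- res$shared_lnc
  }

  ## co-expression on protein-coding genes
  if (.stage_enabled(cfg, "modules")) {
    expr_pc <- norm[intersect(rownames(norm), mrna_ids), , drop = FALSE]
    if (nrow(expr_pc) > cfg$max_module_genes) {
      v <- apply(expr_pc, 1L, var)
      expr_pc <- expr_pc[order(v, decreasing = TRUE)[
        seq_len(cfg$max_module_genes)], , drop = FALSE]
    }
    sft <- suppressWarnings(pick_soft_threshold(expr_pc,
                                                r2_target = cfg$r2_target))
    mods <- detect_modules(expr_pc, sft$beta, cfg$min_module_size)
    traits <- data.frame(
      SF = as.numeric(samples$group == "SF"),
      SC = as.numeric(samples$group == "SC"),
      HF = as.numeric(samples$group == "HF"),
      HC = as.numeric(samples$group == "HC"),
      S = as.numeric(substr(samples$group, 1, 1) == "S"),
      scc = samples$scc)
    mt <- module_trait(mods, traits)
    res$soft_threshold <- sft
    res$modules <- mods
    res$module_trait <- mt
    tables$module_assignment <- mods$assignment
    tables$module_trait <- mt
  }

  ## target prediction for DE lncRNAs (SF vs. SC focus, both reported)
  if (.stage_enabled(cfg, "targets") && length(de)) {
    genes_pc <- reference$genes[reference$genes$biotype %in%
                                  "protein_coding", ]
    gene_of_tx <- setNames(assembly$transcripts$cmp_ref,
                           assembly$transcripts$transcript_id)
    tx_of_ref <- setNames(assembly$transcripts$transcript_id,
                          assembly$transcripts$cmp_ref)
    targ <- list()
    for (cmp in names(de)) {
      d <- de[[cmp]]
      de_lnc_ids <- d$feature_id[d$status != "ns" &
                                   d$feature_type == "lncRNA"]
      de_mrna_ids <- d$feature_id[d$status != "ns" &
                                    d$feature_type == "mRNA"]
      lnc_tab <- res$catalog[res$catalog$transcript_id %in% de_lnc_ids,
                             c("transcript_id", "chrom", "start", "end")]
      # gene spans of the DE mRNAs (gene universe = protein-coding genes)
      gtab <- data.frame(gene_id = genes_pc$gene_id,
                         chrom = genes_pc$chrom,
                         start = genes_pc$start, end = genes_pc$end,
                         stringsAsFactors = FALSE)
      cis <- cis_targets(lnc_tab, gtab, window = cfg$window)
      # keep transcript-level ids for the trans screen
      grp_samples <- samples$sample_id[
        samples$group %in% c(substr(cmp, 1, 2), substr(cmp, 5, 6))]
      grp_samples <- intersect(grp_samples, colnames(norm))
      trans <- trans_targets(norm, de_lnc_ids, de_mrna_ids, grp_samples,
                             r_thr = cfg$r_thr, p_thr = cfg$p_thr)
      # map mRNA transcript ids to reference gene ids for merging with cis
      trans$gene_id <- ifelse(is.na(gene_of_tx[trans$gene_id]),
                              trans$gene_id,
                              sub("\\.\\d+$", "",
                                  gene_of_tx[trans$gene_id]))
      pairs <- merge_target_pairs(cis, trans)
      targ[[cmp]] <- pairs
      tables[[paste0("targets_", cmp)]] <- pairs
    }
    res$targets <- targ

    # binding screen on a bounded number of pairs with available sequences
    if (!is.null(cfg$ndg_max_pairs) && cfg$ndg_max_pairs > 0 &&
        length(targ)) {
      p1 <- targ[[1L]]
      take <- head(seq_len(nrow(p1)), cfg$ndg_max_pairs)
      ndg <- lapply(take, function(i) {
        lseq <- sequences[[p1$lnc_id[i]]]
        gtx <- tx_of_ref[[paste0(p1$gene_id[i], ".1")]]
        tseq <- if (!is.null(gtx) && !is.na(gtx)) sequences[[gtx]] else NULL
        if (is.null(lseq) || is.null(tseq)) return(NULL)
        sc <- ndg_screen(lseq, tseq, cfg$ndg_thr)
        data.frame(lnc_id = p1$lnc_id[i], gene_id = p1$gene_id[i],
                   ndg = sc$ndg, bound = sc$bound,
                   stringsAsFactors = FALSE)
      })
      ndg <- do.call(rbind, ndg)
      if (!is.null(ndg)) {
        res$ndg <- ndg
        tables$binding_screen <- ndg
      }
    }
  }

  ## QTL overlap + GWAS enrichment
  if (.stage_enabled(cfg, "integrate") && length(de)) {
    qtl <- read_table(cfg$qtl, "qtl")
    gwas <- read_table(cfg$gwas, "gwas")
    d <- de$SFvsSC
    de_lnc_ids <- d$feature_id[d$status != "ns" &
                                 d$feature_type == "lncRNA"]
    lnc_tab <- res$catalog[res$catalog$transcript_id %in% de_lnc_ids,
                           c("transcript_id", "chrom", "start", "end")]
    qo <- qtl_overlap(lnc_tab, qtl, window = cfg$window)
    res$qtl_overlap <- qo
    tables$qtl_overlap <- qo

    # gene universe and DE gene sets on assembly transcript coordinates
    atx <- assembly$transcripts
    all_genes <- data.frame(gene_id = atx$transcript_id,
                            chrom = atx$chrom, start = atx$start,
                            end = atx$end, stringsAsFactors = FALSE)
    all_genes <- all_genes[all_genes$gene_id %in%
                             intersect(rownames(filt), mrna_ids), ]
    gw <- list()
    for (cmp in names(de)) {
      dd <- de[[cmp]]
      deg <- intersect(dd$feature_id[dd$status != "ns" &
                                       dd$feature_type == "mRNA"],
                       all_genes$gene_id)
      for (tr in unique(gwas$trait)) {
        if (!length(deg)) next
        enr <- gwas_sum_enrichment(deg, all_genes,
                                   gwas[gwas$trait == tr, ],
                                   ext = cfg$ext, n_perm = cfg$n_perm,
                                   seed = cfg$seed)
        gw[[paste0("DEG-", cmp, "|", tr)]] <-
          data.frame(gene_set = paste0("DEG-", cmp), trait = tr,
                     n_genes = enr$n_genes,
                     observed = enr$observed_stat, emp_p = enr$emp_p,
                     display = enr$display,
                     neglog10_p = enr$neglog10_p,
                     stringsAsFactors = FALSE)
      }
    }
    res$gwas_enrichment <- do.call(rbind, gw)
    tables$gwas_enrichment <- res$gwas_enrichment
  }

  ## over-representation analysis
  if (.stage_enabled(cfg, "ora") && !is.null(cfg$gmt) && length(de)) {
    gmt <- read_table(cfg$gmt, "gmt")
    universe <- rownames(filt)
    ora_res <- list()
    for (cmp in names(de)) {
      dd <- de[[cmp]]
      study <- dd$feature_id[dd$status != "ns"]
      ora_res[[cmp]] <- ora(study, gmt, universe,
                            padj_thr = cfg$ora_padj_thr)
      tables[[paste0("ora_", cmp)]] <- ora_res[[cmp]]
    }
    res$ora <- ora_res
  }

  if (!is.null(cfg$outdir)) {
    params <- cfg[!vapply(cfg, is.null, logical(1))]
    params$stages <- paste(cfg$stages, collapse = ",")
    res$manifest <- write_results(tables, cfg$outdir, params = params)
  }
  res$tables <- tables
  res
}

#' Run the synthetic end-to-end demonstration
#'
#' Generates a complete synthetic dataset, runs the full pipeline on the
#' written files, and scores every stage against the generator's ground
#' truth: lncRNA identification sensitivity/precision, DE sensitivity and
#' empirical FDR per comparison, module recovery (adjusted Rand index),
#' QTL hit recovery, and GWAS enrichment of the planted gene set.
#'
#' @param seed RNG seed for generation and analysis.
#' @param dir scratch directory (a temporary directory by default; removed
#'   on success when created internally).
#' @param n_perm permutations for the GWAS enrichment stage.
#' @return list with `metrics` (named numeric recovery metrics), `result`
#'   (the [run_pipeline()] output) and `truth`.
#' @export
run_demo <- function(seed = 1, dir = NULL, n_perm = 500) {
  own_dir <- is.null(dir)
  if (own_dir) dir <- file.path(tempdir(), paste0("lncmast_demo_", seed))
  ds <- simulate_dataset(seed = seed, dir = dir)
  cfg <- ds$paths[c("assembly_gtf", "reference_gtf", "fasta", "counts",
                    "samples", "qtl", "gwas")]
  cfg$seed <- seed
  cfg$outdir <- file.path(dir, "out")
  cfg$n_perm <- n_perm
  res <- run_pipeline(cfg)
  metrics <- score_against_truth(res, ds$truth)
  if (own_dir) unlink(dir, recursive = TRUE)
  list(metrics = metrics, result = res, truth = ds$truth)
}

#' Score a pipeline result against generator ground truth
#'
#' @param res result of [run_pipeline()] on a synthetic dataset.
#' @param truth ground truth from [simulate_dataset()].
#' @return named numeric vector of recovery metrics.
#' @export
score_against_truth <- function(res, truth) {
  m <- c()
  ## identification
  called <- res$catalog$transcript_id
  true_set <- truth$true_lnc$transcript_id
  tp <- length(intersect(called, true_set))
  m["identify_sensitivity"] <- tp / length(true_set)
  m["identify_precision"] <- if (length(called)) tp / length(called) else NA
  ## DE (per comparison and pooled across both). Genes carrying planted
  ## module or SCC structure are excluded from the false-positive count:
  ## their sample-level latent variation creates real per-realization mean
  ## differences, so they are not null features.
  structured <- c(unlist(lapply(truth$planted_modules, `[[`, "genes"),
                         use.names = FALSE),
                  names(truth$scc_genes))
  tot_called <- 0L; tot_fp <- 0L; tot_strong <- 0L; tot_tp_strong <- 0L
  for (cmp in names(res$de)) {
    d <- res$de[[cmp]]
    called_de <- d$feature_id[d$status != "ns"]
    planted <- names(truth$planted_DE[[cmp]])
    strong <- intersect(planted[abs(truth$planted_DE[[cmp]]) >= 2],
                        d$feature_id)
    m[paste0("de_sensitivity_", cmp)] <-
      length(intersect(called_de, strong)) / max(length(strong), 1)
    called_de <- setdiff(called_de, structured)
    fp <- length(setdiff(called_de, planted))
    m[paste0("de_fdr_", cmp)] <-
      if (length(called_de)) fp / length(called_de) else 0
    tot_called <- tot_called + length(called_de)
    tot_fp <- tot_fp + fp
    tot_strong <- tot_strong + length(strong)
    tot_tp_strong <- tot_tp_strong + length(intersect(called_de, strong))
  }
  if (length(res$de)) {
    m["de_sensitivity"] <- tot_tp_strong / max(tot_strong, 1)
    m["de_fdr"] <- if (tot_called) tot_fp / tot_called else 0
  }
  ## modules: ARI over coding genes whose truth label is module or
  ## background. Planted DE genes are excluded: their shared group-mean
  ## shifts make them genuinely co-expressed, so they are neither
  ## background nor members of a planted module.
  if (!is.null(res$modules) && length(truth$planted_modules)) {
    asg <- res$modules$assignment
    de_genes <- unique(unlist(lapply(truth$planted_DE, names),
                              use.names = FALSE))
    keep <- !(asg$gene %in% de_genes)
    truth_lab <- rep("background", nrow(asg))
    names(truth_lab) <- asg$gene
    for (mn in names(truth$planted_modules)) {
      ids <- intersect(truth$planted_modules[[mn]]$genes, asg$gene)
      truth_lab[ids] <- mn
    }
    if (requireNamespace("mclust", quietly = TRUE)) {
      m["module_ari"] <- mclust::adjustedRandIndex(truth_lab[keep],
                                                   asg$module[keep])
    }
  }
  ## QTL hits
  if (!is.null(res$qtl_overlap) && !is.null(truth$planted_qtl_hits)) {
    hits <- truth$planted_qtl_hits
    de_lnc <- unique(res$qtl_overlap$transcript_id)
    found <- paste(res$qtl_overlap$transcript_id, res$qtl_overlap$qtl_id)
    want <- paste(hits$transcript_id, hits$qtl_id)
    # only hits whose lncRNA was called DE can be recovered downstream
    d <- res$de$SFvsSC
    de_called <- d$feature_id[d$status != "ns"]
    want_reachable <- want[hits$transcript_id %in% de_called]
    m["qtl_hit_recovery"] <- if (length(want_reachable))
      mean(want_reachable %in% found) else NA
  }
  ## GWAS: planted SCS set flagged?
  if (!is.null(res$gwas_enrichment)) {
    g <- res$gwas_enrichment
    row <- g[g$gene_set == "DEG-SFvsSC" &
               g$trait == "Somatic cell score", ]
    if (nrow(row)) m["gwas_scs_emp_p"] <- row$emp_p[1]
  }
  m
}
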