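test_that("QTL overlap retains the worked-example pairs (12 rows, 11 lncRNAs)", {
  tab <- read.delim(example_table("lncrna_qtl_pairs"),
                    colClasses = c(chrom = "character"))
  lnc <- unique(data.frame(transcript_id = tab$transcript_id,
                           chrom = tab$chrom, start = tab$lnc_start,
                           end = tab$lnc_end))
  qtl <- data.frame(chrom = tab$chrom, start = tab$qtl_start,
                    end = tab$qtl_end, trait = tab$qtl_trait,
                    qtl_id = as.character(tab$qtl_id))
  ov <- qtl_overlap(lnc, qtl, window = 100000)
  expect_equal(attr(ov, "n_rows"), 12L)
  expect_equal(attr(ov, "n_distinct_lnc"), 11L)
  # spot-check two printed geometries
  expect_equal(ov$gap[ov$transcript_id == "MSTRG.11108.1"], 35090)
  expect_equal(ov$gap[ov$transcript_id == "MSTRG.11478.1"], 91642)
})

test_that("QTL overlap boundary is exact and monotone in window", {
  lnc <- data.frame(transcript_id = "L", chrom = "1",
                    start = 1000, end = 2000)
  qtl <- data.frame(chrom = "1",
                    start = c(2000 + 100000, 2000 + 100001),
                    end = c(2000 + 100004, 2000 + 100005),
                    trait = "SCS", qtl_id = c("in", "out"))
  ov <- qtl_overlap(lnc, qtl, window = 100000)
  expect_equal(ov$qtl_id, "in")
  expect_equal(ov$gap, 100000)
  # monotone: enlarging the window never drops rows
  wider <- qtl_overlap(lnc, qtl, window = 100002)
  expect_true(all(ov$qtl_id %in% wider$qtl_id))
  expect_equal(nrow(qtl_overlap(lnc[0, ], qtl)), 0L)
})

test_that("GWAS sum enrichment validates inputs and is reproducible", {
  genes <- data.frame(gene_id = sprintf("g%02d", 1:40), chrom = "1",
                      start = seq(1e5, 4e6, length.out = 40),
                      end = seq(1e5, 4e6, length.out = 40) + 2000)
  set.seed(61)
  snps <- data.frame(chrom = "1", pos = round(runif(2000, 1, 4.1e6)),
                     trait = "t", pvalue = runif(2000))
  expect_error(gwas_sum_enrichment(genes$gene_id[1:5], genes, snps,
                                   n_perm = 0), "n_perm")
  expect_warning(r0 <- gwas_sum_enrichment(character(), genes, snps,
                                           n_perm = 10), "empty")
  expect_equal(r0$emp_p, 1)

  r1 <- gwas_sum_enrichment(genes$gene_id[1:8], genes, snps,
                            n_perm = 99, seed = 7)
  r2 <- gwas_sum_enrichment(genes$gene_id[1:8], genes, snps,
                            n_perm = 99, seed = 7)
  expect_identical(r1$null_stats, r2$null_stats)
  expect_identical(r1$emp_p, r2$emp_p)
  # empirical p respects its add-one definition and bounds
  expect_equal(r1$emp_p,
               (1 + sum(r1$null_stats >= r1$observed_stat)) / 100)
  expect_gt(r1$emp_p, 0)
  expect_lte(r1$emp_p, 1)
  expect_gte(r1$display, 0)
  expect_lte(r1$display, log10(2))
})

test_that("planted inflated signal near a gene set is flagged", {
  sim <- generate_annotation(seed = 37)
  samples <- simulate_samples(37)
  cnt <- generate_counts(sim, samples, seed = 37)
  sim$truth <- cnt$truth
  qg <- generate_qtl_gwas(sim, seed = 37)
  atx <- sim$assembly$transcripts
  all_genes <- data.frame(gene_id = atx$transcript_id, chrom = atx$chrom,
                          start = atx$start, end = atx$end)
  all_genes <- all_genes[all_genes$gene_id %in% sim$truth$coding_tx, ]
  scs <- qg$gwas[qg$gwas$trait == "Somatic cell score", ]
  enr <- gwas_sum_enrichment(qg$truth$planted_gwas_genes, all_genes, scs,
                             n_perm = 199, seed = 37)
  expect_lte(enr$emp_p, 0.05)
})

test_that("nearest-SNP report counts boundary-inclusive and matches brute force", {
  set.seed(71)
  genes <- data.frame(gene_id = sprintf("g%02d", 1:50), chrom = "2",
                      start = round(runif(50, 1e5, 5e6)))
  genes$end <- genes$start + 3000
  snps <- data.frame(chrom = "2", pos = round(runif(500, 1, 5.2e6)),
                     trait = "t", pvalue = runif(500)^8)
  ext <- 5e4; thr <- 1e-4
  rep_ <- nearest_snp_report(genes, snps, ext = ext, sig_thr = thr)
  brute <- vapply(seq_len(nrow(genes)), function(g) {
    sum(snps$pvalue < thr &
          snps$pos >= genes$start[g] - ext &
          snps$pos <= genes$end[g] + ext)
  }, integer(1))
  expect_equal(rep_$per_gene$n_significant, brute)

  # SNP exactly at gene_end + ext is counted
  g1 <- data.frame(gene_id = "g", chrom = "1", start = 1000, end = 2000)
  s1 <- data.frame(chrom = "1", pos = 2000 + ext, trait = "t",
                   pvalue = 1e-10)
  expect_equal(nearest_snp_report(g1, s1, ext = ext,
                                  sig_thr = 1e-4)$per_gene$n_significant, 1L)
  # no SNP in range: zero counts
  s2 <- data.frame(chrom = "1", pos = 2000 + ext + 1, trait = "t",
                   pvalue = 1e-10)
  rep2 <- nearest_snp_report(g1, s2, ext = ext, sig_thr = 1e-4)
  expect_equal(rep2$per_gene$n_significant, 0L)
  expect_equal(rep2$manhattan$neglog10_p, 10)
})
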