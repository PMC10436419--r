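test_that("annotation generator respects class geometry and determinism", {
  sim <- generate_annotation(seed = 5, n_coding_genes = 60,
                             n_lnc_per_class = c(u = 8, i = 6, x = 6,
                                                 known = 4))
  tx <- sim$assembly$transcripts

  # only coding genes when no noncoding requested
  sim0 <- generate_annotation(seed = 5, n_coding_genes = 20,
                              n_lnc_per_class = c(u = 0, i = 0, x = 0,
                                                  known = 0), n_other = 0)
  expect_true(all(sim0$assembly$transcripts$class_code == "="))

  # class-i transcripts lie strictly inside an intron of a coding gene
  itx <- tx[tx$class_code == "i", ]
  ref_ex <- sim$reference$exons
  for (r in seq_len(nrow(itx))) {
    host_ex <- ref_ex[ref_ex$chrom == itx$chrom[r], ]
    host_tx <- sim$reference$transcripts
    host_tx <- host_tx[host_tx$chrom == itx$chrom[r] &
                         host_tx$biotype == "protein_coding" &
                         host_tx$start < itx$start[r] &
                         host_tx$end > itx$end[r], ]
    expect_gte(nrow(host_tx), 1L)
    # inside the span but touching no exon of the host
    hex <- host_ex[host_ex$transcript_id %in% host_tx$transcript_id, ]
    overlaps <- hex$start <= itx$end[r] & hex$end >= itx$start[r]
    expect_false(any(overlaps))
  }

  # class-u transcripts at least `window` beyond every gene
  utx <- tx[tx$class_code == "u", ]
  genes <- sim$reference$genes
  for (r in seq_len(nrow(utx))) {
    same <- genes[genes$chrom == utx$chrom[r], ]
    gap <- pmax(0, pmax(same$start, utx$start[r]) -
                  pmin(same$end, utx$end[r]))
    expect_true(all(gap >= sim$truth$window))
  }

  # class-x transcripts overlap a reference exon on the opposite strand
  xtx <- tx[tx$class_code == "x", ]
  for (r in seq_len(nrow(xtx))) {
    hex <- ref_ex[ref_ex$chrom == xtx$chrom[r] &
                    ref_ex$strand != xtx$strand[r], ]
    expect_true(any(hex$start <= xtx$end[r] & hex$end >= xtx$start[r]))
  }

  # determinism: identical seed, identical annotation
  sim2 <- generate_annotation(seed = 5, n_coding_genes = 60,
                              n_lnc_per_class = c(u = 8, i = 6, x = 6,
                                                  known = 4))
  expect_identical(sim$assembly$transcripts, sim2$assembly$transcripts)
  expect_identical(sim$truth, sim2$truth)
})

test_that("annotation generator fails cleanly on an undersized genome", {
  expect_error(generate_annotation(seed = 1, n_coding_genes = 500,
                                   n_chroms = 1, chrom_len = 1e6),
               "too short")
})

test_that("sequences carry coding/noncoding signal at annotated lengths", {
  sim <- generate_annotation(seed = 9, n_coding_genes = 40,
                             n_lnc_per_class = c(u = 10, i = 5, x = 5,
                                                 known = 5))
  seqs <- generate_sequences(sim, seed = 9)
  tx <- sim$assembly$transcripts
  expect_equal(unname(nchar(seqs[tx$transcript_id])), tx$length)

  # coding transcripts of decent length contain a long ORF
  ctx <- tx[tx$transcript_id %in% sim$truth$coding_tx & tx$length >= 900, ]
  orf <- vapply(seqs[ctx$transcript_id],
                function(s) find_orf(s)$length, numeric(1))
  expect_true(all(orf >= 300))

  # noncoding transcripts have only short spurious ORFs
  ln <- sim$truth$true_lnc$transcript_id
  orf_nc <- vapply(seqs[ln], function(s) find_orf(s)$length, numeric(1))
  expect_gte(mean(orf_nc < 150), 0.9)

  # GC stays in a physiological band
  gc <- vapply(seqs, function(s) {
    b <- strsplit(s, "")[[1]]
    mean(b %in% c("G", "C"))
  }, numeric(1))
  expect_true(all(gc >= 0.25 & gc <= 0.72))

  # empty annotation gives empty sequence set
  sim0 <- generate_annotation(seed = 1, n_coding_genes = 5,
                              n_lnc_per_class = c(u = 0, i = 0, x = 0,
                                                  known = 0), n_other = 0)
  sim0$assembly$transcripts <- sim0$assembly$transcripts[0, ]
  expect_length(generate_sequences(sim0, seed = 1), 0L)
})

test_that("count generator plants recoverable effects and structure", {
  sim <- generate_annotation(seed = 21)
  samples <- simulate_samples(21)
  cnt <- generate_counts(sim, samples, seed = 21)
  expect_true(is.integer(cnt$counts))
  expect_equal(colnames(cnt$counts), samples$sample_id)

  # library sizes vary >= 2-fold by design
  sf_true <- cnt$truth$size_factors
  expect_gte(max(sf_true) / min(sf_true), 2)

  # zero-count violators are all-zero rows
  zid <- cnt$truth$violators$transcript_id[
    cnt$truth$violators$violation == "zero_count"]
  if (length(zid))
    expect_true(all(cnt$counts[zid, ] == 0L))

  # a planted +2 effect at high depth is recovered by the DE caller
  filt <- prefilter_counts(cnt$counts)
  groups <- samples$group[match(colnames(filt), samples$sample_id)]
  r <- call_de(nb_wald_test(filt, groups, "SFvsSC"))
  eff <- cnt$truth$planted_DE$SFvsSC
  big <- names(eff)[abs(eff) >= 2 & names(eff) %in% rownames(filt)]
  called <- r$feature_id[r$status != "ns"]
  expect_gte(mean(big %in% called), 0.8)

  # SCC classification rule holds in the sample sheet
  expect_true(all(samples$scc >= 0))
  expect_gt(median(samples$scc[substr(samples$group, 1, 1) == "S"]), 500)

  # fewer than 2 samples per group is an error
  bad <- samples[-c(1:3), ]
  expect_error(generate_counts(sim, bad, seed = 1), "fewer than 2")
})

test_that("size factors recover true library sizes in the near-Poisson regime", {
  sim <- generate_annotation(seed = 13, n_coding_genes = 200,
                             n_lnc_per_class = c(u = 0, i = 0, x = 0,
                                                 known = 0), n_other = 0)
  samples <- simulate_samples(13)
  cnt <- generate_counts(sim, samples, seed = 13, de_config = list(),
                         module_config = NULL, scc_config = NULL,
                         nb_params = list(mu_meanlog = log(500),
                                          mu_sdlog = 0.2,
                                          alpha_meanlog = log(1e-6),
                                          alpha_sdlog = 0.01))
  sf <- size_factors(cnt$counts)
  truth <- cnt$truth$size_factors[names(sf)]
  truth <- truth / exp(mean(log(truth)))
  expect_lt(max(abs(sf / truth - 1)), 0.05)
})

test_that("QTL/GWAS generator plants hits inside and decoys outside the window", {
  sim <- generate_annotation(seed = 31)
  samples <- simulate_samples(31)
  cnt <- generate_counts(sim, samples, seed = 31)
  sim$truth <- cnt$truth
  qg <- generate_qtl_gwas(sim, seed = 31)
  lnc_tab <- sim$assembly$transcripts[
    sim$assembly$transcripts$transcript_id %in%
      sim$truth$true_lnc$transcript_id,
    c("transcript_id", "chrom", "start", "end")]
  ov <- qtl_overlap(lnc_tab, qg$qtl, window = 1e5)
  hits <- qg$truth$planted_qtl_hits
  found <- paste(ov$transcript_id, ov$qtl_id)
  expect_true(all(paste(hits$transcript_id, hits$qtl_id) %in% found))
  # decoy QTLs never appear
  decoy_ids <- setdiff(qg$qtl$qtl_id, hits$qtl_id)
  expect_false(any(ov$qtl_id %in% decoy_ids))
  # p-values valid and the SCS panel carries inflated signal near anchors
  expect_true(all(qg$gwas$pvalue > 0 & qg$gwas$pvalue <= 1))
  expect_identical(generate_qtl_gwas(sim, seed = 31)$qtl, qg$qtl)
})
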