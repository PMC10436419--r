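test_that("cis targets follow the gap rule with strict window boundary", {
  lnc <- data.frame(transcript_id = "L1", chrom = "18",
                    start = 55476038, end = 55476403)
  genes <- data.frame(
    gene_id = c("near", "boundary_out", "boundary_in", "overlap", "otherchr"),
    chrom = c("18", "18", "18", "18", "19"),
    start = c(55440944, 55476403 + 100001, 55476403 + 100000, 55476100,
              55440944),
    end = c(55440948, 55476403 + 100004, 55476403 + 100003, 55476500,
            55440948))
  out <- cis_targets(lnc, genes, window = 100000)
  expect_setequal(out$gene_id, c("near", "boundary_in", "overlap"))
  expect_equal(out$distance[out$gene_id == "near"], 35090)
  expect_equal(out$distance[out$gene_id == "overlap"], 0)
  expect_true(out$proximal[out$gene_id == "overlap"])

  # symmetric in interval roles and monotone in window
  swapped <- cis_targets(
    data.frame(transcript_id = "near", chrom = "18",
               start = 55440944, end = 55440948),
    data.frame(gene_id = "L1", chrom = "18",
               start = 55476038, end = 55476403), window = 100000)
  expect_equal(swapped$distance, 35090)
  narrow <- cis_targets(lnc, genes, window = 30000)
  expect_true(all(narrow$gene_id %in% out$gene_id))
})

test_that("trans targets keep perfect correlations and obey the null rate", {
  # identical and exactly anticorrelated profiles are kept
  x <- rbind(l1 = c(1, 2, 3, 4, 5, 6, 7, 8),
             g1 = c(1, 2, 3, 4, 5, 6, 7, 8),
             g2 = -c(1, 2, 3, 4, 5, 6, 7, 8))
  colnames(x) <- paste0("s", 1:8)
  out <- trans_targets(x, "l1", c("g1", "g2"), colnames(x))
  expect_setequal(out$gene_id, c("g1", "g2"))
  expect_equal(out$pcc[out$gene_id == "g1"], 1)
  expect_equal(out$pcc[out$gene_id == "g2"], -1)

  # retention of pure noise matches the analytic t-tail
  set.seed(31)
  n <- 8; npairs <- 500
  noise <- matrix(rnorm((npairs + 1) * n), ncol = n,
                  dimnames = list(c("lnc", sprintf("g%03d", 1:npairs)),
                                  paste0("s", 1:n)))
  for (r_thr in c(0.7, 0.95)) {
    kept <- trans_targets(noise, "lnc", sprintf("g%03d", 1:npairs),
                          colnames(noise), r_thr = r_thr, p_thr = 0.05)
    # analytic retention probability: |R| above the effective threshold
    r05 <- sqrt(qt(0.975, n - 2)^2 / (qt(0.975, n - 2)^2 + n - 2))
    r_eff <- max(r_thr, r05)
    t_eff <- r_eff * sqrt((n - 2) / (1 - r_eff^2))
    p_keep <- 2 * pt(-t_eff, n - 2)
    expect_lte(nrow(kept), qbinom(0.9995, npairs, p_keep))
    expect_gte(nrow(kept), qbinom(0.0005, npairs, p_keep))
  }

  # zero-variance feature skipped, under 3 samples refused
  flat <- rbind(l1 = rep(1, 8), g1 = rnorm(8))
  colnames(flat) <- paste0("s", 1:8)
  expect_equal(nrow(suppressMessages(
    trans_targets(flat, "l1", "g1", colnames(flat)))), 0L)
  expect_error(trans_targets(x[, 1:2], "l1", "g1", colnames(x)[1:2]),
               ">= 3 samples")
})

test_that("duplex screen scores a perfect complement and shuns random pairs", {
  set.seed(41)
  s <- random_dna(30)
  rc <- chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]),
                                     collapse = ""))
  res <- ndg_screen(s, rc)
  # hand sum of the full stacking path, normalized by length
  expect_equal(res$ndg, oracle_stack_sum(s) / 30, tolerance = 1e-12)
  expect_true(res$bound)
  expect_lt(res$ndg, -0.8)

  # threshold is strict: at exactly the computed ndg, not bound
  res2 <- ndg_screen(s, rc, ndg_thr = res$ndg)
  expect_false(res2$bound)

  # random sequences of the same composition are rarely bound
  set.seed(42)
  hits <- vapply(1:200, function(i) {
    a <- random_dna(300)
    b <- random_dna(300)
    ndg_screen(a, b)$bound
  }, logical(1))
  expect_gte(mean(!hits), 0.95)

  expect_error(ndg_screen("ACGT", rc), ">= 20 nt")
  expect_error(ndg_screen(strrep("Z", 30), rc), "ACGT/ACGU")
})

test_that("SCC regression finds exact and planted relations, rejects constants", {
  scc <- c(100, 200, 300, 400, 500, 600)
  r <- scc_regression(2 * scc, scc)
  expect_equal(r$r, 1)
  expect_equal(r$slope, 2)
  expect_lt(r$pvalue, 1e-10)
  expect_error(scc_regression(rnorm(4), rep(5, 4)), "constant")
  expect_error(scc_regression(rnorm(2), c(1, 2)), ">= 3 samples")

  # permutation calibration: with random SCC the slope p is uniform
  set.seed(51)
  expr <- rnorm(12)
  p <- vapply(1:400, function(i)
    scc_regression(expr, sample(seq(50, 900, length.out = 12)))$pvalue,
    numeric(1))
  expect_lt(abs(mean(p < 0.05) - 0.05), 0.04)

  # a planted SCC-linked gene in synthetic data is significant
  sim <- generate_annotation(seed = 29, n_coding_genes = 100,
                             n_lnc_per_class = c(u = 0, i = 0, x = 0,
                                                 known = 0), n_other = 0)
  samples <- simulate_samples(29)
  cnt <- generate_counts(sim, samples, seed = 29, de_config = list(),
                         module_config = NULL)
  norm <- normalized_log(prefilter_counts(cnt$counts))
  gs <- intersect(names(cnt$truth$scc_genes), rownames(norm))
  pvals <- vapply(gs, function(g)
    scc_regression(norm[g, ], samples$scc)$pvalue, numeric(1))
  expect_gte(mean(pvals < 0.05), 0.6)
})

test_that("pair merging and network assembly conserve structure", {
  cis <- data.frame(lnc_id = c("L1", "L1"), gene_id = c("A", "B"),
                    mode = "cis", distance = c(0, 500), proximal = TRUE)
  trans <- data.frame(lnc_id = c("L1", "L2"), gene_id = c("B", "C"),
                      mode = "trans", pcc = c(0.99, -0.97),
                      pcc_p = c(0.001, 0.002))
  pairs <- merge_target_pairs(cis, trans)
  expect_equal(nrow(pairs), 3L)
  both <- pairs[pairs$lnc_id == "L1" & pairs$gene_id == "B", ]
  expect_equal(both$mode, "both")
  expect_equal(both$distance, 500)
  expect_equal(both$pcc, 0.99)

  hits <- data.frame(term = c("path1", "path1"), gene_id = c("A", "B"))
  net <- build_network(pairs, de_status = c(A = "up", C = "down"),
                       pathway_hits = hits)
  expect_equal(sum(net$edges$type == "lnc-gene"), nrow(pairs))
  expect_equal(sum(net$edges$type == "gene-pathway"), 2L)
  expect_equal(net$nodes$de_status[net$nodes$id == "A"], "up")
  # empty targets give an empty network
  net0 <- build_network(pairs[0, ])
  expect_equal(nrow(net0$edges), 0L)
})
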