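test_that("find_orf reads single-codon and framed ORFs correctly", {
  expect_equal(find_orf("ATGAAATAA")$length, 9L)
  # ties break to the 5'-most start; stop codon included in the length
  s <- paste0("CC", "ATG", "AAACCC", "TAG", "GG")   # off-frame ORF of 12 nt
  orf <- find_orf(s)
  expect_equal(orf$length, 12L)
  expect_equal(orf$start, 3L)
  expect_equal(substr(orf$orf_seq, 1, 3), "ATG")
  # no stop codon, no ORF
  expect_equal(find_orf("ATGAAAAAAAAA")$length, 0L)
  expect_equal(find_orf("ACGT")$length, 0L)
})

test_that("hexamer score is zero for identical tables and separates classes", {
  tabs <- default_hexamer_tables()
  same <- list(coding = tabs$coding, noncoding = tabs$coding)
  expect_equal(hexamer_score("ATGAAACCCGGGTTTACGTAG", same), 0)

  set.seed(1)
  sim <- generate_annotation(seed = 2, n_coding_genes = 30,
                             n_lnc_per_class = c(u = 10, i = 0, x = 0,
                                                 known = 0), n_other = 0)
  seqs <- generate_sequences(sim, seed = 2)
  hx_cod <- vapply(seqs[sim$truth$coding_tx], hexamer_score, numeric(1),
                   tables = tabs)
  hx_lnc <- vapply(seqs[sim$truth$true_lnc$transcript_id], hexamer_score,
                   numeric(1), tables = tabs)
  expect_gt(mean(hx_cod), 0)
  expect_lt(mean(hx_lnc), mean(hx_cod))
})

test_that("Fickett statistic matches an independent transcription", {
  set.seed(7)
  seqs <- c(random_dna(300),
            random_dna(300, p = c(0.4, 0.1, 0.1, 0.4)),
            paste0("ATG", paste(rep("GCC", 98), collapse = ""), "TAA"))
  for (s in seqs) {
    expect_equal(fickett_score(s), oracle_fickett(s), tolerance = 1e-12)
  }
})

test_that("consensus_call equals brute-force set intersection", {
  set.seed(11)
  n <- 100
  scores <- data.frame(
    transcript_id = sprintf("t%03d", 1:n),
    orf_length = sample(c(50, 200, 400), n, replace = TRUE),
    fickett = runif(n, 0.5, 1.3),
    hexamer = runif(n, -2, 2),
    composite = runif(n))
  ext <- data.frame(transcript_id = scores$transcript_id,
                    plek = runif(n, -1, 1), cnci = runif(n, -1, 1))
  got <- consensus_call(scores, external = ext)
  sets <- list(
    scores$transcript_id[scores$orf_length < 300],
    scores$transcript_id[scores$fickett < 0.95],
    scores$transcript_id[scores$hexamer < 0],
    scores$transcript_id[scores$composite < 0.5],
    ext$transcript_id[ext$plek < 0],
    ext$transcript_id[ext$cnci < 0])
  expect_setequal(got, Reduce(intersect, sets))

  # one coding-voting predictor excludes the transcript
  one <- data.frame(transcript_id = "x", orf_length = 0, fickett = 0,
                    hexamer = -1, composite = 0.9)
  expect_length(consensus_call(one), 0L)

  # missing external entry is conservatively coding
  ext2 <- data.frame(transcript_id = "other", plek = -1)
  all_nc <- data.frame(transcript_id = "x", orf_length = 0, fickett = 0,
                       hexamer = -1, composite = 0.1)
  expect_warning(out <- consensus_call(all_nc, external = ext2),
                 "missing")
  expect_length(out, 0L)
})

test_that("score_coding_potential validates sequences", {
  expect_error(score_coding_potential(c(a = "ACGTX")), "non-ACGTN")
  expect_warning(
    score_coding_potential(c(a = paste0(strrep("N", 10), strrep("ACGT", 10)))),
    "N fraction")
})

test_that("basic filter enforces exon/length/count rules with known bypass", {
  tx <- data.frame(
    transcript_id = c("one_exon_novel", "short2", "ok_boundary",
                      "known_one_exon", "no_counts"),
    gene_id = "g", chrom = "1", strand = "+",
    start = 1, end = 1000,
    length = c(500, 199, 200, 500, 400),
    exon_count = c(1L, 2L, 2L, 1L, 2L),
    class_code = c("u", "u", "u", "=", "u"),
    cmp_ref = NA, biotype = NA, stringsAsFactors = FALSE)
  counts <- matrix(c(5, 5, 1, 5, 0), ncol = 1,
                   dimnames = list(tx$transcript_id, "s1"))
  kept <- basic_filter(tx, counts, known_lnc_ids = "known_one_exon")
  expect_setequal(kept$transcript_id,
                  c("ok_boundary", "known_one_exon"))
  # monotone: output is a subset of input
  expect_true(all(kept$transcript_id %in% tx$transcript_id))
})

test_that("class codes partition and classify into a total partition", {
  ref <- list(transcripts = data.frame(
    transcript_id = c("L1.1", "P1.1"),
    biotype = c("lncRNA", "protein_coding"), stringsAsFactors = FALSE))
  tx <- data.frame(
    transcript_id = c("u1", "i1", "x1", "j1", "eq_lnc", "eq_pc"),
    class_code = c("u", "i", "x", "j", "=", "="),
    cmp_ref = c(NA, NA, NA, NA, "L1.1", "P1.1"),
    stringsAsFactors = FALSE)
  parts <- suppressMessages(class_code_filter(tx, ref))
  expect_setequal(parts$novel$transcript_id, c("u1", "i1", "x1"))
  expect_equal(parts$known$transcript_id, "eq_lnc")
  expect_setequal(names(parts$discarded), c("j", "="))

  cat <- classify_lncrna(parts$novel, parts$known)
  expect_equal(nrow(cat), 4L)
  expect_equal(cat$category[match(c("u1", "i1", "x1", "eq_lnc"),
                                  cat$transcript_id)],
               c("lincRNA", "ilncRNA", "lncNAT", "known"))
  expect_false(any(duplicated(cat$transcript_id)))
  expect_true(all(cat$novel[cat$category != "known"]))
})

test_that("feature_report conserves catalog counts", {
  cat <- data.frame(transcript_id = sprintf("t%d", 1:10),
                    length = c(rep(300, 8), 2000, 1500),
                    exon_count = c(rep(2L, 6), rep(3L, 4)),
                    chrom = rep(c("1", "2"), 5),
                    novel = rep(c(TRUE, FALSE), 5),
                    category = rep(c("lincRNA", "known"), 5),
                    stringsAsFactors = FALSE)
  rep_ <- feature_report(cat)
  expect_equal(sum(rep_$exon_hist), 10)
  expect_equal(sum(rep_$length_bins), 10)
  expect_equal(sum(rep_$per_chrom), 10)
  expect_equal(unname(rep_$length_bins[["[200,1500]"]]), 9)
  # all lengths in one bin
  cat2 <- cat; cat2$length <- 300
  expect_equal(unname(feature_report(cat2)$length_bins[["[200,1500]"]]), 10)
  # per-chromosome counts match a direct groupby
  expect_equal(as.vector(rep_$per_chrom),
               as.vector(table(cat$chrom)))
  # empty catalog: empty report, no error
  expect_equal(sum(feature_report(cat[0, ])$exon_hist), 0)
})

test_that("identification recovers the planted catalog on synthetic data", {
  sim <- generate_annotation(seed = 17)
  seqs <- generate_sequences(sim, seed = 17)
  samples <- simulate_samples(17)
  cnt <- generate_counts(sim, samples, seed = 17)
  ident <- suppressMessages(
    identify_lncrnas(sim$assembly, sim$reference, seqs, cnt$counts))
  called <- ident$catalog$transcript_id
  truth <- sim$truth$true_lnc$transcript_id
  expect_gte(length(intersect(called, truth)) / length(truth), 0.9)
  expect_gte(length(intersect(called, truth)) / length(called), 0.9)
  # category counts match planted categories for the recovered transcripts
  got <- ident$catalog$category[match(intersect(called, truth), called)]
  want <- sim$truth$true_lnc$category[
    match(intersect(called, truth), truth)]
  expect_equal(got, want)
  # filters are monotone: catalog is a subset of the filtered set
  expect_true(all(called %in% ident$filtered$transcript_id))
})
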