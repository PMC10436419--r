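# helper: expression with planted correlated blocks
make_block_expr <- function(seed, n_modules = 3, module_size = 50,
                            n_noise = 60, n_samples = 12, within_sd = 0.45) {
  set.seed(seed)
  rows <- list()
  labs <- character()
  for (m in seq_len(n_modules)) {
    f <- rnorm(n_samples)
    block <- t(vapply(seq_len(module_size), function(i)
      sample(c(-1, 1), 1) * f + rnorm(n_samples, 0, within_sd),
      numeric(n_samples)))
    rows[[m]] <- block
    labs <- c(labs, rep(paste0("m", m), module_size))
  }
  noise <- matrix(rnorm(n_noise * n_samples), n_noise, n_samples)
  x <- rbind(do.call(rbind, rows), noise)
  rownames(x) <- sprintf("g%03d", seq_len(nrow(x)))
  labs <- c(labs, rep("bg", n_noise))
  names(labs) <- rownames(x)
  list(expr = x, labels = labs)
}

test_that("soft threshold prefers small powers for clean block structure", {
  fx <- make_block_expr(1, n_modules = 2, module_size = 40, n_noise = 20,
                        within_sd = 0.2)
  sft <- suppressWarnings(pick_soft_threshold(fx$expr, betas = 1:12))
  expect_s3_class(sft, "SoftThresholdResult")
  expect_true(sft$beta %in% 1:12)
  expect_equal(nrow(sft$candidates), 12)
  expect_true(all(sft$candidates$r2 <= 1, na.rm = TRUE))
  # under 4 samples is refused
  expect_error(pick_soft_threshold(fx$expr[, 1:3]), ">= 4 samples")
})

test_that("degenerate equal-correlation input takes the warning path", {
  # two samples' worth of structure replicated: all pairwise cor identical
  x <- matrix(rep(c(1, 2, 3, 4), each = 10), nrow = 10)
  x <- x + matrix(rep(seq(0, 0.9, 0.1), 4), nrow = 10)
  expect_warning(pick_soft_threshold(x), "undefined|no candidate")
})

test_that("TOM is a similarity: unit diagonal, symmetric, in [0,1]", {
  fx <- make_block_expr(2, n_modules = 2, module_size = 30, n_noise = 10)
  a <- abs(cor(t(fx$expr)))^6
  diag(a) <- 0
  tom <- tom_similarity(a)
  expect_equal(unname(diag(tom)), rep(1, nrow(tom)))
  expect_equal(tom, t(tom))
  expect_true(all(tom >= 0 & tom <= 1 + 1e-12))
})

test_that("module detection recovers planted blocks and ignores gene order", {
  fx <- make_block_expr(3)
  mods <- detect_modules(fx$expr, beta = 6)
  skip_if_not_installed("mclust")
  ari <- mclust::adjustedRandIndex(fx$labels[mods$assignment$gene],
                                   mods$assignment$module)
  expect_gte(ari, 0.8)

  # permutation invariance of membership
  perm <- sample(nrow(fx$expr))
  mods2 <- detect_modules(fx$expr[perm, ], beta = 6)
  m1 <- setNames(mods$assignment$module, mods$assignment$gene)
  m2 <- setNames(mods2$assignment$module, mods2$assignment$gene)
  expect_equal(mclust::adjustedRandIndex(m1[names(m2)], m2), 1)
})

test_that("a single repeated profile forms one module", {
  set.seed(5)
  f <- rnorm(10)
  x <- t(vapply(1:60, function(i) f + rnorm(10, 0, 0.1), numeric(10)))
  rownames(x) <- sprintf("g%02d", 1:60)
  mods <- detect_modules(x, beta = 6, min_module_size = 30)
  expect_equal(length(mods$members), 1L)
  expect_equal(sort(unname(lengths(mods$members))), 60L)
})

test_that("eigengene is PC1-optimal and sign-oriented", {
  fx <- make_block_expr(6, n_modules = 1, module_size = 40, n_noise = 0)
  me <- module_eigengene(fx$expr)
  x <- t(scale(t(fx$expr)))
  # mean orientation is positive
  expect_gt(mean(cor(me, t(x))), 0)
  # PC1 explains at least as much summed squared correlation as any member
  ss_me <- sum(cor(me, t(x))^2)
  ss_best_member <- max(vapply(seq_len(nrow(x)), function(j)
    sum(cor(x[j, ], t(x))^2, na.rm = TRUE), numeric(1)))
  expect_gte(ss_me + 1e-8, ss_best_member)
})

test_that("module-trait correlation behaves under identity and sign flip", {
  fx <- make_block_expr(7, n_modules = 1, module_size = 40, n_noise = 0,
                        within_sd = 0.2)
  mods <- detect_modules(fx$expr, beta = 4)
  skip_if(length(mods$members) == 0)
  me <- mods$eigengenes[, 1]
  traits <- data.frame(exact = me, flipped = -me,
                       const = rep(1, length(me)))
  mt <- module_trait(mods, traits)
  r_exact <- mt$r[mt$trait == "exact"][1]
  r_flip <- mt$r[mt$trait == "flipped"][1]
  expect_equal(r_exact, 1)
  expect_equal(r_flip, -1)
  expect_equal(mt$pvalue[mt$trait == "exact"][1],
               mt$pvalue[mt$trait == "flipped"][1])
  expect_true(is.na(mt$r[mt$trait == "const"][1]))
})

test_that("the group-linked planted module is detected and significant", {
  sim <- generate_annotation(seed = 23, n_coding_genes = 200,
                             n_lnc_per_class = c(u = 0, i = 0, x = 0,
                                                 known = 0), n_other = 0)
  samples <- simulate_samples(23)
  cnt <- generate_counts(sim, samples, seed = 23, de_config = list(),
                         scc_config = NULL)
  norm <- normalized_log(prefilter_counts(cnt$counts))
  sft <- suppressWarnings(pick_soft_threshold(norm))
  mods <- detect_modules(norm, sft$beta)
  traits <- data.frame(S = as.numeric(substr(samples$group, 1, 1) == "S"))
  mt <- module_trait(mods, traits)
  # the module carrying the group-tied factor correlates with S
  m1_genes <- cnt$truth$planted_modules$planted_1$genes
  overlap <- vapply(mods$members, function(g)
    length(intersect(g, m1_genes)) / length(m1_genes), numeric(1))
  best <- names(which.max(overlap))
  expect_gte(overlap[[best]], 0.8)
  row <- mt[mt$module == best & mt$trait == "S", ]
  expect_lt(row$pvalue, 0.05)
  expect_gt(abs(row$r), 0.5)
})
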