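# Shared fixtures and independent oracle implementations used across tests.

# tiny two-transcript assembly GTF written as literal text
write_toy_assembly_gtf <- function(path) {
  lines <- c(
    paste0("1\tStringTie\texon\t101\t200\t.\t+\t.\t",
           'gene_id "MSTRG.1"; transcript_id "MSTRG.1.1"; class_code "u";'),
    paste0("1\tStringTie\texon\t301\t400\t.\t+\t.\t",
           'gene_id "MSTRG.1"; transcript_id "MSTRG.1.1"; class_code "u";'),
    paste0("2\tStringTie\texon\t1000\t1999\t.\t-\t.\t",
           'gene_id "MSTRG.2"; transcript_id "MSTRG.2.1";'))
  writeLines(lines, path)
  path
}

# Independent transcription of the Fickett TESTCODE procedure, written as
# literal per-base loops (deliberately different structure from the package
# implementation).
oracle_fickett <- function(seq) {
  pos_prob <- list(
    A = c(0.94, 0.68, 0.84, 0.93, 0.58, 0.68, 0.45, 0.34, 0.20, 0.22),
    C = c(0.80, 0.70, 0.70, 0.81, 0.66, 0.48, 0.51, 0.33, 0.30, 0.23),
    G = c(0.90, 0.88, 0.74, 0.64, 0.53, 0.48, 0.27, 0.16, 0.08, 0.08),
    T = c(0.97, 0.97, 0.91, 0.68, 0.69, 0.44, 0.54, 0.20, 0.09, 0.09))
  pos_w <- c(A = 0.26, C = 0.18, G = 0.31, T = 0.33)
  con_prob <- list(
    A = c(0.28, 0.49, 0.44, 0.55, 0.62, 0.49, 0.67, 0.65, 0.81, 0.21),
    C = c(0.82, 0.64, 0.51, 0.64, 0.59, 0.59, 0.43, 0.44, 0.39, 0.31),
    G = c(0.40, 0.54, 0.47, 0.64, 0.64, 0.73, 0.41, 0.41, 0.33, 0.29),
    T = c(0.28, 0.24, 0.39, 0.40, 0.55, 0.75, 0.56, 0.69, 0.51, 0.58))
  con_w <- c(A = 0.11, C = 0.12, G = 0.15, T = 0.14)
  ch <- strsplit(toupper(seq), "")[[1]]
  total <- 0
  for (b in c("A", "C", "G", "T")) {
    n1 <- 0; n2 <- 0; n3 <- 0
    for (i in seq_along(ch)) {
      if (ch[i] != b) next
      r <- i %% 3
      if (r == 1) n1 <- n1 + 1
      else if (r == 2) n2 <- n2 + 1
      else n3 <- n3 + 1
    }
    position <- max(n1, n2, n3) / (min(n1, n2, n3) + 1)
    content <- (n1 + n2 + n3) / length(ch)
    pcuts <- c(1.9, 1.8, 1.7, 1.6, 1.5, 1.4, 1.3, 1.2, 1.1, 0)
    pv <- NA
    for (j in seq_along(pcuts)) {
      if (position >= pcuts[j]) { pv <- pos_prob[[b]][j]; break }
    }
    ccuts <- c(0.33, 0.31, 0.29, 0.27, 0.25, 0.23, 0.21, 0.19, 0.17, 0)
    cv <- NA
    for (j in seq_along(ccuts)) {
      if (content >= ccuts[j]) { cv <- con_prob[[b]][j]; break }
    }
    total <- total + pv * pos_w[[b]] + cv * con_w[[b]]
  }
  total
}

# hand step-up BH oracle
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  adj <- rep(NA_real_, m)
  prev <- Inf
  rank_desc <- m:1
  for (idx in seq_along(o)) {
    i <- o[idx]
    val <- p[i] * m / rank_desc[idx]
    prev <- min(prev, val)
    adj[i] <- min(prev, 1)
  }
  adj
}

# exact hypergeometric upper-tail by enumeration
oracle_hyper_tail <- function(k, K, n, N) {
  tot <- 0
  for (j in k:min(K, n)) {
    tot <- tot + choose(K, j) * choose(N - K, n - j)
  }
  tot / choose(N, n)
}

# stack energies for the duplex-screen oracle (direct hand sum)
oracle_stack_sum <- function(seq) {
  e <- c(AA = -0.93, UU = -0.93, AU = -1.10, UA = -1.33,
         CU = -2.08, AG = -2.08, CA = -2.11, UG = -2.11,
         GU = -2.24, AC = -2.24, GA = -2.35, UC = -2.35,
         CG = -2.36, GG = -3.26, CC = -3.26, GC = -3.42)
  s <- chartr("T", "U", toupper(seq))
  tot <- 0
  for (i in 1:(nchar(s) - 1)) {
    tot <- tot + e[[substr(s, i, i + 1)]]
  }
  tot
}

random_dna <- function(n, p = c(0.25, 0.25, 0.25, 0.25)) {
  paste0(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = p),
         collapse = "")
}
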