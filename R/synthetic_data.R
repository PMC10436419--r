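## Ground-truthed synthetic data: annotation, transcript sequences, NB
## counts with planted differential expression / co-expression modules /
## SCC-linked genes, QTL intervals and GWAS SNPs. Every generator is a pure
## function of (configuration, seed), and the returned ground truth is
## sufficient to score each downstream stage.

#' Default sample sheet for the four-group design
#'
#' Four groups: subclinical-mastitis folic-acid-fed (SF) and control (SC),
#' healthy fed (HF) and control (HC). SCC (somatic cell count, x1000
#' cells/mL) is drawn log-normal with median 600 for the S groups and 100
#' for the H groups, matching the > 500 x 1000 cells/mL classification rule
#' for subclinical mastitis.
#'
#' @param seed RNG seed.
#' @param n_per_group named integer vector of samples per group.
#' @return data.frame `sample_id`, `group`, `scc`.
#' @export
simulate_samples <- function(seed = 1,
                             n_per_group = c(SF = 4, SC = 4, HF = 3, HC = 3)) {
  stopifnot(all(names(n_per_group) %in% c("SF", "SC", "HF", "HC")))
  set.seed(seed)
  groups <- rep(names(n_per_group), n_per_group)
  ids <- unlist(lapply(names(n_per_group), function(g)
    paste0(g, seq_len(n_per_group[[g]]))), use.names = FALSE)
  med <- ifelse(substr(groups, 1, 1) == "S", 600, 100)
  scc <- rlnorm(length(groups), meanlog = log(med), sdlog = 0.4)
  data.frame(sample_id = ids, group = groups, scc = round(scc, 1),
             stringsAsFactors = FALSE)
}

#' Generate a ground-truthed synthetic annotation
#'
#' Lays out coding genes and four classes of noncoding transcripts on a
#' small multi-chromosome genome:
#' \itemize{
#'   \item class `u` (intergenic) transcripts at least `window` bp beyond
#'     any gene;
#'   \item class `i` (intronic) strictly inside an intron of a host coding
#'     gene;
#'   \item class `x` (antisense) overlapping a host exon on the opposite
#'     strand;
#'   \item class `=` (known) matching a reference transcript with biotype
#'     `"lncRNA"`.
#' }
#' Coding genes also appear in the assembly as class `=` transcripts
#' matching `protein_coding` reference entries, and a handful of class `j`
#' fragments exercise the discard path. A fraction `violator_frac` of the
#' noncoding transcripts is deliberately generated to fail exactly one
#' identification filter (single exon, length < 200 nt, zero counts, or
#' coding-like sequence) so the filters have work to do; these are recorded
#' in the ground truth and excluded from the true catalog.
#'
#' @param seed RNG seed.
#' @param n_coding_genes number of protein-coding genes.
#' @param n_lnc_per_class named counts for classes `u`, `i`, `x`, `known`.
#' @param n_chroms,chrom_len genome shape.
#' @param violator_frac fraction of noncoding transcripts planted as filter
#'   violators.
#' @param window cis/QTL window (bp), controls the intergenic desert.
#' @param n_other number of class `j` decoy fragments.
#' @return list with `assembly` and `reference` ([read_gtf()]-style
#'   `AnnotationBundle`s) and `truth` (ground-truth list with
#'   `true_lnc`, `violators`, `coding_tx`, `window`).
#' @export
generate_annotation <- function(seed = 1, n_coding_genes = 300,
                                n_lnc_per_class = c(u = 40, i = 25, x = 35,
                                                    known = 20),
                                n_chroms = 3, chrom_len = 5e6,
                                violator_frac = 0.15, window = 1e5,
                                n_other = 10) {
  set.seed(seed)
  stopifnot(all(c("u", "i", "x", "known") %in% names(n_lnc_per_class)),
            all(n_lnc_per_class >= 0))
  chroms <- as.character(seq_len(n_chroms))
  n_known <- n_lnc_per_class[["known"]]

  # slot layout: coding genes and known lncRNA genes share the gene region
  occupants <- c(rep("coding", n_coding_genes), rep("known", n_known))
  occ_chrom <- rep(chroms, length.out = length(occupants))
  occupants <- occupants[order(occ_chrom)]
  occ_chrom <- sort(occ_chrom)
  region_start <- 5e4
  region_end <- 0.6 * chrom_len
  per_chrom <- table(factor(occ_chrom, levels = chroms))
  slot_w <- setNames((region_end - region_start) /
                       pmax(as.integer(per_chrom), 1L), chroms)
  if (any(as.integer(per_chrom) > 0 & slot_w < 1.3e4))
    stop("chromosome too short to place requested features; ",
         "increase chrom_len or n_chroms")

  # violator assignment, chosen up front so structure can reflect it
  n_noncoding <- sum(n_lnc_per_class)
  classes <- c(rep("u", n_lnc_per_class[["u"]]),
               rep("i", n_lnc_per_class[["i"]]),
               rep("x", n_lnc_per_class[["x"]]),
               rep("known", n_known))
  violation <- rep(NA_character_, n_noncoding)
  if (n_noncoding > 0 && violator_frac > 0) {
    n_viol <- round(violator_frac * n_noncoding)
    vi <- sample(n_noncoding, n_viol)
    for (v in vi) {
      opts <- if (classes[v] == "known") c("short", "zero_count")
              else c("one_exon", "short", "zero_count", "coding_like")
      violation[v] <- sample(opts, 1L)
    }
  }

  mstrg <- 0L
  next_mstrg <- function() {
    mstrg <<- mstrg + 1L
    sprintf("MSTRG.%d.1", mstrg)
  }
  ref_tx <- list(); ref_ex <- list()
  asm_tx <- list(); asm_ex <- list()
  genes_by_chrom <- lapply(setNames(chroms, chroms), function(x) list())

  add_tx <- function(store, id, gene, chrom, strand, ex_start, ex_end,
                     class_code = NA_character_, cmp_ref = NA_character_,
                     biotype = NA_character_) {
    class_code <- as.character(class_code)
    cmp_ref <- as.character(cmp_ref)
    biotype <- as.character(biotype)
    list(tx = data.frame(transcript_id = id, gene_id = gene, chrom = chrom,
                         strand = strand, start = min(ex_start),
                         end = max(ex_end),
                         length = sum(ex_end - ex_start + 1),
                         exon_count = length(ex_start),
                         class_code = class_code, cmp_ref = cmp_ref,
                         biotype = biotype, stringsAsFactors = FALSE),
         ex = data.frame(transcript_id = id, chrom = chrom, strand = strand,
                         start = ex_start, end = ex_end,
                         stringsAsFactors = FALSE))
  }

  # exon chain from a start position
  chain <- function(start, ex_len, intron_len) {
    s <- integer(length(ex_len)); e <- integer(length(ex_len))
    pos <- start
    for (k in seq_along(ex_len)) {
      s[k] <- pos; e[k] <- pos + ex_len[k] - 1L
      if (k < length(ex_len)) pos <- e[k] + intron_len[k] + 1L
    }
    list(start = s, end = e)
  }

  gi <- 0L; ki <- 0L
  slot_idx <- stats::ave(seq_along(occupants), occ_chrom, FUN = seq_along)
  for (o in seq_along(occupants)) {
    chrom <- occ_chrom[o]
    base <- region_start + (slot_idx[o] - 1) * slot_w[[chrom]] +
      sample(0:2000, 1L)
    strand <- sample(c("+", "-"), 1L)
    if (occupants[o] == "coding") {
      gi <- gi + 1L
      gene <- sprintf("GENE%05d", gi)
      rid <- paste0(gene, ".1")
      n_ex <- sample(3:6, 1L)
      ex_len <- sample(150:400, n_ex, replace = TRUE)
      in_len <- sample(700:1500, n_ex - 1L, replace = TRUE)
      ch <- chain(round(base), ex_len, in_len)
      rec <- add_tx(NULL, rid, gene, chrom, strand, ch$start, ch$end,
                    biotype = "protein_coding")
      ref_tx[[length(ref_tx) + 1L]] <- rec$tx
      ref_ex[[length(ref_ex) + 1L]] <- rec$ex
      aid <- next_mstrg()
      arec <- add_tx(NULL, aid, sub("\\.1$", "", aid), chrom, strand,
                     ch$start, ch$end, class_code = "=", cmp_ref = rid)
      asm_tx[[length(asm_tx) + 1L]] <- arec$tx
      asm_ex[[length(asm_ex) + 1L]] <- arec$ex
      genes_by_chrom[[chrom]][[length(genes_by_chrom[[chrom]]) + 1L]] <-
        list(gene = gene, tx = rid, asm = aid, strand = strand,
             ex_start = ch$start, ex_end = ch$end)
    } else {
      ki <- ki + 1L
      gene <- sprintf("LNCG%04d", ki)
      rid <- paste0(gene, ".1")
      v <- violation[classes == "known"][ki]
      if (!is.na(v) && v == "short") {
        ex_len <- sample(120:190, 1L); in_len <- integer()
      } else {
        n_ex <- sample(1:3, 1L)     # single-exon known lncRNAs are real
        ex_len <- sample(250:800, n_ex, replace = TRUE)
        in_len <- if (n_ex > 1L) sample(300:800, n_ex - 1L, replace = TRUE)
                  else integer()
      }
      ch <- chain(round(base), ex_len, in_len)
      rec <- add_tx(NULL, rid, gene, chrom, strand, ch$start, ch$end,
                    biotype = "lncRNA")
      ref_tx[[length(ref_tx) + 1L]] <- rec$tx
      ref_ex[[length(ref_ex) + 1L]] <- rec$ex
      aid <- next_mstrg()
      arec <- add_tx(NULL, aid, sub("\\.1$", "", aid), chrom, strand,
                     ch$start, ch$end, class_code = "=", cmp_ref = rid)
      asm_tx[[length(asm_tx) + 1L]] <- arec$tx
      asm_ex[[length(asm_ex) + 1L]] <- arec$ex
    }
  }

  noncoding_records <- data.frame(transcript_id = character(),
                                  category = character(),
                                  violation = character(),
                                  stringsAsFactors = FALSE)
  # known lncRNAs enter the record table from the loop above
  known_ids <- vapply(asm_tx, function(t)
    if (!is.na(t$class_code) && t$class_code == "=" &&
        grepl("^LNCG", t$cmp_ref)) t$transcript_id else NA_character_,
    character(1))
  known_ids <- known_ids[!is.na(known_ids)]
  vio_known <- violation[classes == "known"]
  if (length(known_ids))
    noncoding_records <- rbind(noncoding_records, data.frame(
      transcript_id = known_ids, category = "known",
      violation = vio_known, stringsAsFactors = FALSE))

  pick_host <- function(chrom) {
    hosts <- genes_by_chrom[[chrom]]
    hosts[[sample(length(hosts), 1L)]]
  }

  # intronic (class i): strictly inside a host intron
  vio_i <- violation[classes == "i"]
  for (j in seq_len(n_lnc_per_class[["i"]])) {
    chrom <- sample(chroms, 1L)
    host <- pick_host(chrom)
    while (length(host$ex_start) < 2L) host <- pick_host(chrom)
    intr <- sample(length(host$ex_start) - 1L, 1L)
    i_start <- host$ex_end[intr] + 1L
    i_end <- host$ex_start[intr + 1L] - 1L
    avail <- i_end - i_start + 1L - 40L       # 20 bp margin each side
    v <- vio_i[j]
    if (!is.na(v) && v == "short") {
      ex_len <- min(sample(120:190, 1L), avail); in_len <- integer()
    } else if (!is.na(v) && v == "one_exon") {
      ex_len <- min(sample(250:500, 1L), avail); in_len <- integer()
    } else {
      gap <- 60L
      half <- (avail - gap) %/% 2L
      ex_len <- pmin(sample(120:250, 2L, replace = TRUE), half)
      in_len <- gap
    }
    ch <- chain(i_start + 20L, ex_len, in_len)
    aid <- next_mstrg()
    rec <- add_tx(NULL, aid, sub("\\.1$", "", aid), chrom,
                  host$strand, ch$start, ch$end, class_code = "i")
    asm_tx[[length(asm_tx) + 1L]] <- rec$tx
    asm_ex[[length(asm_ex) + 1L]] <- rec$ex
    noncoding_records <- rbind(noncoding_records, data.frame(
      transcript_id = aid, category = "ilncRNA", violation = v,
      stringsAsFactors = FALSE))
  }

  # antisense (class x): overlaps a host exon on the opposite strand
  vio_x <- violation[classes == "x"]
  for (j in seq_len(n_lnc_per_class[["x"]])) {
    chrom <- sample(chroms, 1L)
    host <- pick_host(chrom)
    strand <- if (host$strand == "+") "-" else "+"
    anchor <- host$ex_start[1L]
    v <- vio_x[j]
    if (!is.na(v) && v == "short") {
      ex_len <- sample(120:190, 1L); in_len <- integer()
      start <- anchor - sample(20:60, 1L)
    } else if (!is.na(v) && v == "one_exon") {
      ex_len <- sample(250:600, 1L); in_len <- integer()
      start <- anchor - sample(50:150, 1L)
    } else {
      ex_len <- sample(150:400, 2L, replace = TRUE)
      in_len <- sample(200:600, 1L)
      start <- anchor - sample(50:150, 1L)
    }
    ch <- chain(max(1L, start), ex_len, in_len)
    aid <- next_mstrg()
    rec <- add_tx(NULL, aid, sub("\\.1$", "", aid), chrom, strand,
                  ch$start, ch$end, class_code = "x")
    asm_tx[[length(asm_tx) + 1L]] <- rec$tx
    asm_ex[[length(asm_ex) + 1L]] <- rec$ex
    noncoding_records <- rbind(noncoding_records, data.frame(
      transcript_id = aid, category = "lncNAT", violation = v,
      stringsAsFactors = FALSE))
  }

  # intergenic (class u): in the desert, >= window beyond any gene
  vio_u <- violation[classes == "u"]
  n_u <- n_lnc_per_class[["u"]]
  if (n_u > 0) {
    u_chrom <- sort(rep(chroms, length.out = n_u))
    desert_start <- region_end + window + 1e4
    desert_end <- chrom_len - 6e5
    if (desert_end - desert_start < 1e4 * max(table(u_chrom)))
      stop("chromosome too short for the intergenic desert; ",
           "increase chrom_len")
    u_idx <- stats::ave(seq_len(n_u), u_chrom, FUN = seq_along)
    u_slot <- setNames(
      (desert_end - desert_start) /
        pmax(as.integer(table(factor(u_chrom, levels = chroms))), 1L),
      chroms)
    for (j in seq_len(n_u)) {
      chrom <- u_chrom[j]
      base <- desert_start + (u_idx[j] - 1) * u_slot[[chrom]] +
        sample(0:1000, 1L)
      strand <- sample(c("+", "-"), 1L)
      v <- vio_u[j]
      if (!is.na(v) && v == "short") {
        ex_len <- sample(120:190, 1L); in_len <- integer()
      } else if (!is.na(v) && v == "one_exon") {
        ex_len <- sample(250:800, 1L); in_len <- integer()
      } else {
        n_ex <- sample(2:3, 1L)
        ex_len <- sample(150:600, n_ex, replace = TRUE)
        in_len <- sample(300:900, n_ex - 1L, replace = TRUE)
      }
      ch <- chain(round(base), ex_len, in_len)
      aid <- next_mstrg()
      rec <- add_tx(NULL, aid, sub("\\.1$", "", aid), chrom, strand,
                    ch$start, ch$end, class_code = "u")
      asm_tx[[length(asm_tx) + 1L]] <- rec$tx
      asm_ex[[length(asm_ex) + 1L]] <- rec$ex
      noncoding_records <- rbind(noncoding_records, data.frame(
        transcript_id = aid, category = "lincRNA", violation = v,
        stringsAsFactors = FALSE))
    }
  }

  # class-j decoys overlapping genes (discarded by the class-code filter)
  for (j in seq_len(n_other)) {
    chrom <- sample(chroms, 1L)
    host <- pick_host(chrom)
    ex_len <- sample(150:400, 2L, replace = TRUE)
    ch <- chain(host$ex_start[1L] + sample(10:50, 1L), ex_len,
                sample(200:500, 1L))
    aid <- next_mstrg()
    rec <- add_tx(NULL, aid, sub("\\.1$", "", aid), chrom, host$strand,
                  ch$start, ch$end, class_code = "j")
    asm_tx[[length(asm_tx) + 1L]] <- rec$tx
    asm_ex[[length(asm_ex) + 1L]] <- rec$ex
  }

  order_bundle <- function(tx, ex, source) {
    tx <- do.call(rbind, tx); ex <- do.call(rbind, ex)
    tx <- tx[order(tx$transcript_id), , drop = FALSE]
    ex <- ex[order(ex$transcript_id, ex$start), , drop = FALSE]
    rownames(tx) <- NULL; rownames(ex) <- NULL
    sp <- split(seq_len(nrow(tx)), tx$gene_id)
    genes <- data.frame(
      gene_id = names(sp),
      chrom = vapply(sp, function(i) tx$chrom[i[1L]], character(1)),
      start = vapply(sp, function(i) min(tx$start[i]), numeric(1)),
      end = vapply(sp, function(i) max(tx$end[i]), numeric(1)),
      strand = vapply(sp, function(i) tx$strand[i[1L]], character(1)),
      biotype = vapply(sp, function(i) {
        b <- tx$biotype[i]; b <- b[!is.na(b)]
        if (length(b)) b[[1L]] else NA_character_
      }, character(1)), stringsAsFactors = FALSE)
    rownames(genes) <- NULL
    .new_annotation_bundle(tx, ex, genes, source)
  }

  assembly <- order_bundle(asm_tx, asm_ex, "assembly")
  reference <- order_bundle(ref_tx, ref_ex, "reference")
  truth <- list(
    true_lnc = .reset_rows(noncoding_records[
      is.na(noncoding_records$violation),
      c("transcript_id", "category")]),
    violators = .reset_rows(noncoding_records[
      !is.na(noncoding_records$violation), , drop = FALSE]),
    coding_tx = vapply(asm_tx, function(t)
      if (!is.na(t$class_code) && t$class_code == "=" &&
          grepl("^GENE", t$cmp_ref)) t$transcript_id else NA_character_,
      character(1)),
    window = window)
  truth$coding_tx <- truth$coding_tx[!is.na(truth$coding_tx)]
  list(assembly = assembly, reference = reference, truth = truth)
}

.sample_bases <- function(n, p = c(A = 0.3, C = 0.2, G = 0.2, T = 0.3)) {
  paste0(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

.sample_codons <- function(n_codons) {
  usage <- .codon_usage
  usage[.stop_codons] <- 0
  paste0(sample(names(usage), n_codons, replace = TRUE,
                prob = usage / sum(usage)), collapse = "")
}

# destroy ORFs >= max_orf by replacing their middle codon with a stop
.break_orfs <- function(seq, max_orf = 150, max_iter = 100) {
  for (it in seq_len(max_iter)) {
    orf <- find_orf(seq)
    if (orf$length < max_orf) break
    mid <- orf$start + 3L * ((orf$length / 3L) %/% 2L)
    substr(seq, mid, mid + 2L) <- "TAA"
  }
  seq
}

#' Generate transcript sequences matching the synthetic annotation
#'
#' Coding transcripts (and noncoding transcripts planted as `coding_like`
#' violators) receive an embedded long ORF (>= 300 nt where the length
#' permits) with codon usage drawn from the mammalian codon-usage table
#' and flanking UTRs; all other noncoding transcripts are drawn from a
#' mildly AT-rich i.i.d. composition and post-processed so that no ORF
#' reaches 150 nt. Sequence length equals the annotated transcript length.
#'
#' @param sim result of [generate_annotation()].
#' @param seed RNG seed.
#' @return named character vector of DNA sequences, one per assembly
#'   transcript.
#' @export
generate_sequences <- function(sim, seed = 1) {
  set.seed(seed)
  tx <- sim$assembly$transcripts
  if (!nrow(tx)) return(setNames(character(), character()))
  coding_like <- c(sim$truth$coding_tx,
                   sim$truth$violators$transcript_id[
                     sim$truth$violators$violation == "coding_like"])
  out <- setNames(character(nrow(tx)), tx$transcript_id)
  for (r in seq_len(nrow(tx))) {
    L <- tx$length[r]
    id <- tx$transcript_id[r]
    if (id %in% coding_like && L >= 360L) {
      orf_len <- max(300L, 3L * ((0.7 * L) %/% 3L))
      orf_len <- min(orf_len, 3L * ((L - 60L) %/% 3L))
      utr5 <- (L - orf_len) %/% 2L
      utr3 <- L - orf_len - utr5
      stopc <- sample(.stop_codons, 1L,
                      prob = .codon_usage[.stop_codons])
      orf <- paste0("ATG", .sample_codons(orf_len / 3L - 2L), stopc)
      s5 <- if (utr5 > 0) .sample_bases(utr5, rep(0.25, 4) |>
                                          setNames(c("A", "C", "G", "T")))
            else ""
      s3 <- if (utr3 > 0) .sample_bases(utr3, rep(0.25, 4) |>
                                          setNames(c("A", "C", "G", "T")))
            else ""
      seqs <- paste0(s5, orf, s3)
      # guard: no upstream ORF longer than the embedded one
      out[r] <- seqs
    } else {
      out[r] <- .break_orfs(.sample_bases(L))
    }
  }
  out
}

#' Generate NB counts with planted signal
#'
#' Counts are negative binomial with per-feature baseline means drawn
#' log-normal and dispersions log-normal around 0.1. Library size factors
#' span a >= 2-fold range. Planted structure:
#' \itemize{
#'   \item differential expression: selected features get their mean
#'     multiplied by `2^effect` in the treatment group of their comparison
#'     (effects drawn from `lfc_range` with random sign, a subset planted
#'     in both comparisons);
#'   \item co-expression modules: groups of coding transcripts share a
#'     latent factor tied to the S (subclinical mastitis) vs. H (healthy)
#'     contrast;
#'   \item SCC-linked genes: expression linear in standardized log SCC.
#' }
#' Features planted as `zero_count` violators get all-zero rows.
#'
#' @param sim result of [generate_annotation()].
#' @param samples sample sheet from [simulate_samples()].
#' @param seed RNG seed.
#' @param de_config list with `n_mrna`, `n_lnc`, `n_shared`, `lfc_range`,
#'   `min_mu` (set `list()` for a fully null matrix).
#' @param module_config list with `n_modules`, `module_size`, `latent_sd`
#'   (noise sd of the group-tied first module's latent factor); `NULL`
#'   disables modules. The first module is strongly tied to the S/H
#'   contrast; later modules get mostly independent latent factors so that
#'   modules remain mutually separable.
#' @param scc_config list with `n_genes`, `effect`; `NULL` disables.
#' @param nb_params list with `mu_meanlog`, `mu_sdlog`, `alpha_meanlog`,
#'   `alpha_sdlog`.
#' @return list with `counts` (integer matrix), `truth` (the input truth
#'   augmented with `planted_DE`, `planted_modules`, `scc_genes`,
#'   `size_factors`).
#' @export
generate_counts <- function(sim, samples = simulate_samples(seed),
                            seed = 1,
                            de_config = list(n_mrna = 40, n_lnc = 12,
                                             n_shared = 10,
                                             lfc_range = c(2, 3.5),
                                             min_mu = 100),
                            module_config = list(n_modules = 3,
                                                 module_size = 50,
                                                 latent_sd = 0.3),
                            scc_config = list(n_genes = 10, effect = 0.8),
                            nb_params = list(mu_meanlog = log(300),
                                             mu_sdlog = 1,
                                             alpha_meanlog = log(0.1),
                                             alpha_sdlog = 0.5)) {
  set.seed(seed + 1L)
  tab <- table(samples$group)
  if (any(tab < 2L))
    stop("fewer than 2 samples in group(s): ",
         paste(names(tab)[tab < 2L], collapse = ", "))
  tx_ids <- sim$assembly$transcripts$transcript_id
  n_feat <- length(tx_ids); n_samp <- nrow(samples)
  mu <- rlnorm(n_feat, nb_params$mu_meanlog, nb_params$mu_sdlog)
  mu <- pmax(mu, 5)
  alpha <- rlnorm(n_feat, nb_params$alpha_meanlog, nb_params$alpha_sdlog)
  names(mu) <- names(alpha) <- tx_ids

  # library size factors spanning >= 2-fold
  sf <- exp(seq(log(0.65), log(1.45), length.out = n_samp))
  sf <- sample(sf)
  names(sf) <- samples$sample_id

  log2mu <- matrix(0, n_feat, n_samp, dimnames = list(tx_ids,
                                                      samples$sample_id))
  truth <- sim$truth
  coding <- truth$coding_tx
  lnc <- truth$true_lnc$transcript_id

  planted_DE <- list()
  used <- character()
  pick_de <- function(pool, n) {
    avail <- setdiff(pool, used)
    if (length(avail) < n)
      stop("not enough unplanted features left to plant ", n,
           " more; reduce de_config/module_config/scc_config or ",
           "generate more features")
    sample(avail, n)
  }
  if (length(de_config)) {
    shared_m <- pick_de(coding, min(de_config$n_shared,
                                    de_config$n_mrna))
    used <- c(used, shared_m)
    shared_l <- pick_de(lnc, min(max(de_config$n_shared %/% 3, 2),
                                 de_config$n_lnc))
    used <- c(used, shared_l)
    for (cmp in c("SFvsSC", "HFvsHC")) {
      own_m <- pick_de(coding, de_config$n_mrna - length(shared_m))
      used <- c(used, own_m)
      own_l <- pick_de(lnc, de_config$n_lnc - length(shared_l))
      used <- c(used, own_l)
      feats <- c(shared_m, shared_l, own_m, own_l)
      eff <- sample(c(-1, 1), length(feats), replace = TRUE) *
        runif(length(feats), de_config$lfc_range[1], de_config$lfc_range[2])
      names(eff) <- feats
      planted_DE[[cmp]] <- eff
      trt <- substr(cmp, 1, 2)
      cols <- samples$group == trt
      log2mu[feats, cols] <- log2mu[feats, cols] + eff
      mu[feats] <- pmax(mu[feats], de_config$min_mu)
    }
  }

  planted_modules <- list()
  if (!is.null(module_config)) {
    s_ind <- ifelse(substr(samples$group, 1, 1) == "S", 0.5, -0.5)
    for (m in seq_len(module_config$n_modules)) {
      genes_m <- pick_de(coding, module_config$module_size)
      used <- c(used, genes_m)
      # first module strongly tied to the S/H contrast; later modules get
      # mostly independent latent factors (weak group tie) so modules stay
      # separable while the group-linked module remains detectable
      f <- if (m == 1L)
        s_ind + rnorm(n_samp, 0, module_config$latent_sd)
      else
        0.3 * s_ind + rnorm(n_samp, 0, 0.65)
      b <- sample(c(-1, 1), length(genes_m), replace = TRUE) *
        runif(length(genes_m), 0.8, 1.2)
      log2mu[genes_m, ] <- log2mu[genes_m, ] + outer(b, f)
      mu[genes_m] <- pmax(mu[genes_m], 500)
      alpha[genes_m] <- pmin(alpha[genes_m], 0.02)
      planted_modules[[paste0("planted_", m)]] <-
        list(genes = genes_m, trait = "S")
    }
  }

  scc_genes <- numeric()
  if (!is.null(scc_config)) {
    gs <- pick_de(coding, scc_config$n_genes)
    used <- c(used, gs)
    z <- as.numeric(scale(log(samples$scc)))
    sl <- sample(c(-1, 1), length(gs), replace = TRUE) * scc_config$effect
    log2mu[gs, ] <- log2mu[gs, ] + outer(sl, z)
    mu[gs] <- pmax(mu[gs], 100)
    scc_genes <- setNames(sl, gs)
  }

  mu_mat <- mu * 2^log2mu
  mu_mat <- sweep(mu_mat, 2L, sf, "*")
  counts <- matrix(rnbinom(n_feat * n_samp, mu = as.vector(mu_mat),
                           size = rep(1 / pmax(alpha, 1e-8), n_samp)),
                   n_feat, n_samp,
                   dimnames = list(tx_ids, samples$sample_id))
  zero_ids <- truth$violators$transcript_id[
    truth$violators$violation == "zero_count"]
  counts[rownames(counts) %in% zero_ids, ] <- 0L
  storage.mode(counts) <- "integer"

  truth$planted_DE <- planted_DE
  truth$planted_modules <- planted_modules
  truth$scc_genes <- scc_genes
  truth$size_factors <- sf
  list(counts = counts, truth = truth)
}

#' Generate QTL intervals and GWAS SNPs with planted structure
#'
#' Chosen lncRNAs receive a short QTL interval within the +/- `window` bp
#' overlap criterion (planted hits); decoy QTLs are placed in a reserved
#' chromosome tail at least `window` bp from every transcript. GWAS SNPs
#' are uniform over the genome with uniform p-values, except SNPs within
#' +/- `ext` bp of the planted enriched genes, whose p-values are drawn
#' from a non-central chi-squared signal.
#'
#' @param sim result of [generate_annotation()] (after
#'   [generate_counts()] if planted DE genes should anchor the GWAS
#'   signal).
#' @param truth ground-truth list (defaults to `sim$truth`), used to pick
#'   DE lncRNAs/genes as anchors when available.
#' @param seed RNG seed.
#' @param n_hits,n_decoys planted and decoy QTL counts.
#' @param window QTL overlap window (bp).
#' @param n_snps_per_trait SNPs per trait.
#' @param n_inflated_genes coding genes anchoring the inflated GWAS signal
#'   for the "Somatic cell score" trait.
#' @param ext GWAS extension window (bp).
#' @param ncp non-centrality of the planted chi-squared signal.
#' @param chrom_len as in [generate_annotation()].
#' @return list with `qtl` and `gwas` tables plus `truth` augmented with
#'   `planted_qtl_hits` (transcript/qtl pairs) and `planted_gwas_genes`.
#' @export
generate_qtl_gwas <- function(sim, truth = sim$truth, seed = 1,
                              n_hits = 8, n_decoys = 10, window = 1e5,
                              n_snps_per_trait = 6000,
                              n_inflated_genes = 15, ext = 5e4, ncp = 12,
                              chrom_len = 5e6) {
  set.seed(seed + 2L)
  tx <- sim$assembly$transcripts
  lnc_pool <- truth$true_lnc$transcript_id
  de_lnc <- unique(unlist(lapply(truth$planted_DE, function(e)
    intersect(names(e), lnc_pool)), use.names = FALSE))
  anchors <- if (length(de_lnc) >= n_hits) sample(de_lnc, n_hits)
             else c(de_lnc, sample(setdiff(lnc_pool, de_lnc),
                                   n_hits - length(de_lnc)))
  traits <- c("Somatic cell score", "Somatic cell count",
              "Clinical mastitis")
  qtl_rows <- list(); hit_rows <- list()
  qid <- 10000L
  for (a in anchors) {
    row <- tx[tx$transcript_id == a, ]
    gap <- sample.int(round(0.9 * window), 1L)
    side <- sample(c("left", "right"), 1L)
    if (side == "right") {
      qs <- row$end + gap
    } else {
      qs <- max(1, row$start - gap - 4)
    }
    qid <- qid + 1L
    qtl_rows[[length(qtl_rows) + 1L]] <- data.frame(
      chrom = row$chrom, start = qs, end = qs + 4,
      trait = sample(traits, 1L), qtl_id = as.character(qid),
      stringsAsFactors = FALSE)
    hit_rows[[length(hit_rows) + 1L]] <- data.frame(
      transcript_id = a, qtl_id = as.character(qid),
      stringsAsFactors = FALSE)
  }
  # decoys in the reserved tail, > window away from every transcript
  chroms <- unique(tx$chrom)
  for (d in seq_len(n_decoys)) {
    chrom <- sample(chroms, 1L)
    qs <- round(runif(1, chrom_len - 3.5e5, chrom_len - 1e4))
    same <- tx[tx$chrom == chrom, ]
    gaps <- .gap_bp(same$start, same$end, qs, qs + 4)
    stopifnot(all(gaps > window))
    qid <- qid + 1L
    qtl_rows[[length(qtl_rows) + 1L]] <- data.frame(
      chrom = chrom, start = qs, end = qs + 4,
      trait = sample(traits, 1L), qtl_id = as.character(qid),
      stringsAsFactors = FALSE)
  }
  qtl <- do.call(rbind, qtl_rows)

  # GWAS: one SNP panel per trait; SCS carries the planted signal
  genes <- sim$assembly$transcripts[
    sim$assembly$transcripts$transcript_id %in% truth$coding_tx, ]
  de_genes <- intersect(names(truth$planted_DE$SFvsSC), truth$coding_tx)
  gw_anchor <- if (length(de_genes) >= n_inflated_genes)
    sample(de_genes, n_inflated_genes) else
      c(de_genes, sample(setdiff(truth$coding_tx, de_genes),
                         n_inflated_genes - length(de_genes)))
  snp_traits <- c("Somatic cell score", "Milk yield")
  gwas <- do.call(rbind, lapply(snp_traits, function(tr) {
    chrom <- sample(chroms, n_snps_per_trait, replace = TRUE)
    pos <- round(runif(n_snps_per_trait, 1, chrom_len))
    p <- runif(n_snps_per_trait)
    data.frame(chrom = chrom, pos = pos, trait = tr, pvalue = p,
               stringsAsFactors = FALSE)
  }))
  scs <- gwas$trait == "Somatic cell score"
  a_tx <- tx[tx$transcript_id %in% gw_anchor, ]
  sgr <- GenomicRanges::GRanges(gwas$chrom[scs],
                                IRanges::IRanges(gwas$pos[scs],
                                                 gwas$pos[scs]))
  agr <- GenomicRanges::GRanges(
    a_tx$chrom, IRanges::IRanges(pmax(1, a_tx$start - ext),
                                 a_tx$end + ext))
  near <- unique(S4Vectors::queryHits(
    GenomicRanges::findOverlaps(sgr, agr, ignore.strand = TRUE)))
  if (length(near)) {
    x2 <- rchisq(length(near), df = 1, ncp = ncp)
    gwas$pvalue[which(scs)[near]] <-
      pmax(pchisq(x2, df = 1, lower.tail = FALSE), 1e-300)
  }
  truth$planted_qtl_hits <- do.call(rbind, hit_rows)
  truth$planted_gwas_genes <- gw_anchor
  list(qtl = qtl, gwas = gwas, truth = truth)
}

#' Generate a complete synthetic dataset
#'
#' Convenience wrapper chaining [generate_annotation()],
#' [generate_sequences()], [simulate_samples()], [generate_counts()] and
#' [generate_qtl_gwas()] under one seed. When `dir` is given, all inputs
#' are also written in the on-disk formats the pipeline reads (GTFs, FASTA,
#' TSV tables, ground truth as JSON).
#'
#' @param seed RNG seed controlling every draw.
#' @param dir optional output directory.
#' @param counts_args optional named list overriding [generate_counts()]
#'   arguments (`de_config`, `module_config`, `scc_config`, `nb_params`).
#' @param ... passed to [generate_annotation()].
#' @return list with `assembly`, `reference`, `sequences`, `samples`,
#'   `counts`, `qtl`, `gwas`, `truth`, and (when written) `paths`.
#' @export
simulate_dataset <- function(seed = 1, dir = NULL, counts_args = list(),
                             ...) {
  sim <- generate_annotation(seed = seed, ...)
  sequences <- generate_sequences(sim, seed = seed)
  samples <- simulate_samples(seed = seed)
  cnt <- do.call(generate_counts,
                 c(list(sim = sim, samples = samples, seed = seed),
                   counts_args))
  sim$truth <- cnt$truth
  qg <- generate_qtl_gwas(sim, seed = seed)
  out <- list(assembly = sim$assembly, reference = sim$reference,
              sequences = sequences, samples = samples,
              counts = cnt$counts, qtl = qg$qtl, gwas = qg$gwas,
              truth = qg$truth)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(
      assembly_gtf = file.path(dir, "assembly.gtf"),
      reference_gtf = file.path(dir, "reference.gtf"),
      fasta = file.path(dir, "transcripts.fa"),
      counts = file.path(dir, "counts.tsv"),
      samples = file.path(dir, "samples.tsv"),
      qtl = file.path(dir, "qtl.tsv"),
      gwas = file.path(dir, "gwas.tsv"),
      truth = file.path(dir, "truth.json"))
    write_gtf(out$assembly, paths$assembly_gtf)
    write_gtf(out$reference, paths$reference_gtf)
    Biostrings::writeXStringSet(
      Biostrings::DNAStringSet(out$sequences), paths$fasta)
    cnt_df <- data.frame(feature_id = rownames(out$counts),
                         as.data.frame(out$counts), check.names = FALSE)
    write.table(cnt_df, paths$counts, sep = "\t", quote = FALSE,
                row.names = FALSE)
    write.table(out$samples, paths$samples, sep = "\t", quote = FALSE,
                row.names = FALSE)
    write.table(out$qtl, paths$qtl, sep = "\t", quote = FALSE,
                row.names = FALSE)
    write.table(out$gwas, paths$gwas, sep = "\t", quote = FALSE,
                row.names = FALSE)
    jsonlite::write_json(.truth_json(out$truth), paths$truth,
                         auto_unbox = TRUE, digits = NA)
    out$paths <- paths
  }
  out
}

.truth_json <- function(truth) {
  list(true_lnc = truth$true_lnc,
       violators = truth$violators,
       coding_tx = truth$coding_tx,
       planted_DE = lapply(truth$planted_DE, as.list),
       planted_modules = truth$planted_modules,
       scc_genes = as.list(truth$scc_genes),
       size_factors = as.list(truth$size_factors),
       planted_qtl_hits = truth$planted_qtl_hits,
       planted_gwas_genes = truth$planted_gwas_genes,
       window = truth$window)
}

#' Write an AnnotationBundle as GTF
#'
#' Emits one exon row per exon with the attributes matching the bundle's
#' dialect (`class_code`/`cmp_ref` for assemblies,
#' `gene_biotype`/`transcript_biotype` for references), readable back by
#' [read_gtf()].
#'
#' @param bundle an `AnnotationBundle`.
#' @param path output file path.
#' @return (invisibly) the path.
#' @export
write_gtf <- function(bundle, path) {
  tx <- bundle$transcripts
  ex <- bundle$exons
  src <- if (bundle$source == "assembly") "StringTie" else "ensembl"
  idx <- match(ex$transcript_id, tx$transcript_id)
  attrs <- sprintf('gene_id "%s"; transcript_id "%s";',
                   tx$gene_id[idx], ex$transcript_id)
  if (bundle$source == "assembly") {
    cc <- tx$class_code[idx]
    has_cc <- !is.na(cc)
    attrs[has_cc] <- paste0(attrs[has_cc],
                            sprintf(' class_code "%s";', cc[has_cc]))
    cr <- tx$cmp_ref[idx]
    has_cr <- !is.na(cr)
    attrs[has_cr] <- paste0(attrs[has_cr],
                            sprintf(' cmp_ref "%s";', cr[has_cr]))
  } else {
    bio <- tx$biotype[idx]
    has_b <- !is.na(bio)
    attrs[has_b] <- paste0(attrs[has_b],
                           sprintf(' gene_biotype "%s"; transcript_biotype "%s";',
                                   bio[has_b], bio[has_b]))
  }
  lines <- sprintf("%s\t%s\texon\t%d\t%d\t.\t%s\t.\t%s",
                   ex$chrom, src, as.integer(ex$start), as.integer(ex$end),
                   ex$strand, attrs)
  writeLines(lines, path)
  invisible(path)
}
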