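## Built-in coding-potential scorers. Four independent signals are computed
## per transcript (longest-ORF length, Fickett TESTCODE statistic, in-frame
## hexamer usage log-ratio, and a composite logistic score) and combined by
## strict intersection, mirroring the common practice of calling a transcript
## noncoding only when every predictor agrees.

# Fickett (1982) TESTCODE lookup tables. Position parameter: for each base,
# max/(min+1) of its counts in the three codon positions; content parameter:
# base fraction. Each parameter maps through a 10-bin probability lookup and
# the eight probabilities combine with fixed weights.
.fickett_position_prob <- list(
  A = c(0.94, 0.68, 0.84, 0.93, 0.58, 0.68, 0.45, 0.34, 0.20, 0.22),
  C = c(0.80, 0.70, 0.70, 0.81, 0.66, 0.48, 0.51, 0.33, 0.30, 0.23),
  G = c(0.90, 0.88, 0.74, 0.64, 0.53, 0.48, 0.27, 0.16, 0.08, 0.08),
  T = c(0.97, 0.97, 0.91, 0.68, 0.69, 0.44, 0.54, 0.20, 0.09, 0.09))
.fickett_position_weight <- c(A = 0.26, C = 0.18, G = 0.31, T = 0.33)
.fickett_position_cut <- c(1.9, 1.8, 1.7, 1.6, 1.5, 1.4, 1.3, 1.2, 1.1, 0)
.fickett_content_prob <- list(
  A = c(0.28, 0.49, 0.44, 0.55, 0.62, 0.49, 0.67, 0.65, 0.81, 0.21),
  C = c(0.82, 0.64, 0.51, 0.64, 0.59, 0.59, 0.43, 0.44, 0.39, 0.31),
  G = c(0.40, 0.54, 0.47, 0.64, 0.64, 0.73, 0.41, 0.41, 0.33, 0.29),
  T = c(0.28, 0.24, 0.39, 0.40, 0.55, 0.75, 0.56, 0.69, 0.51, 0.58))
.fickett_content_weight <- c(A = 0.11, C = 0.12, G = 0.15, T = 0.14)
.fickett_content_cut <- c(0.33, 0.31, 0.29, 0.27, 0.25, 0.23, 0.21, 0.19,
                          0.17, 0)

.stop_codons <- c("TAA", "TAG", "TGA")

#' Find the longest open reading frame
#'
#' Scans the three forward frames of a transcript sequence for ORFs that
#' begin with ATG and end with an in-frame stop codon (TAA/TAG/TGA).
#' Transcript sequences are assumed already oriented, so the reverse strand
#' is not scanned. The longest ORF wins; ties break to the 5'-most start.
#'
#' @param seq a single DNA sequence (character).
#' @return list with `length` (nt, stop codon included; 0 if no ORF),
#'   `start`, `end` (1-based, NA if no ORF) and `orf_seq`.
#' @export
find_orf <- function(seq) {
  seq <- toupper(as.character(seq))
  n <- nchar(seq)
  best <- list(length = 0L, start = NA_integer_, end = NA_integer_,
               orf_seq = "")
  if (n < 6L) return(best)
  for (frame in 0:2) {
    starts <- seq.int(1L + frame, n - 2L, by = 3L)
    if (length(starts) < 2L) next
    codons <- substring(seq, starts, starts + 2L)
    is_atg <- codons == "ATG"
    is_stop <- codons %in% .stop_codons
    if (!any(is_atg) || !any(is_stop)) next
    stop_idx <- which(is_stop)
    for (a in which(is_atg)) {
      s_after <- stop_idx[stop_idx > a]
      if (!length(s_after)) next
      len <- (s_after[1L] - a + 1L) * 3L
      if (len > best$length) {
        best$length <- len
        best$start <- starts[a]
        best$end <- starts[a] + len - 1L
      }
    }
  }
  if (best$length > 0L)
    best$orf_seq <- substring(seq, best$start, best$end)
  best
}

.fickett_lookup <- function(value, cuts, probs) {
  probs[which(value >= cuts)[1L]]
}

#' Fickett TESTCODE statistic
#'
#' Computes the classical TESTCODE statistic from base-position asymmetry
#' and base composition, using the published 10-bin probability lookup
#' tables. Values near or above 0.95 indicate protein-coding character.
#'
#' @param seq a single DNA sequence (character).
#' @return the TESTCODE statistic (numeric scalar).
#' @export
fickett_score <- function(seq) {
  seq <- toupper(as.character(seq))
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  keep <- chars %in% c("A", "C", "G", "T")
  chars <- chars[keep]
  n <- length(chars)
  if (n < 3L) return(0)
  pos <- (seq_len(n) - 1L) %% 3L
  score <- 0
  for (b in c("A", "C", "G", "T")) {
    cnt <- c(sum(chars == b & pos == 0L),
             sum(chars == b & pos == 1L),
             sum(chars == b & pos == 2L))
    posval <- max(cnt) / (min(cnt) + 1)
    content <- sum(cnt) / n
    score <- score +
      .fickett_lookup(posval, .fickett_position_cut,
                      .fickett_position_prob[[b]]) *
        .fickett_position_weight[[b]] +
      .fickett_lookup(content, .fickett_content_cut,
                      .fickett_content_prob[[b]]) *
        .fickett_content_weight[[b]]
  }
  unname(score)
}

.all_hexamers <- function() {
  b <- c("A", "C", "G", "T")
  g <- expand.grid(b, b, b, b, b, b, stringsAsFactors = FALSE)[, 6:1]
  sort(apply(g, 1L, paste0, collapse = ""))
}

#' Train hexamer frequency tables
#'
#' Counts in-frame hexamers (step 3, starting at position 1) in a set of
#' coding sequences (assumed frame-aligned CDS) and a set of noncoding
#' sequences, returning pseudocount-smoothed frequency tables for use by
#' [hexamer_score()].
#'
#' @param coding_seqs,noncoding_seqs character vectors of DNA sequences.
#' @param pseudocount added to every hexamer count before normalization.
#' @return list with `coding` and `noncoding`: named numeric vectors of
#'   frequencies over all 4096 hexamers (each sums to 1).
#' @export
train_hexamer <- function(coding_seqs, noncoding_seqs, pseudocount = 1) {
  hx <- .all_hexamers()
  count_set <- function(seqs) {
    tab <- setNames(rep(pseudocount, length(hx)), hx)
    for (s in seqs) {
      s <- toupper(as.character(s))
      n <- nchar(s)
      if (n < 6L) next
      starts <- seq.int(1L, n - 5L, by = 3L)
      hexes <- substring(s, starts, starts + 5L)
      hexes <- hexes[!grepl("[^ACGT]", hexes)]
      t2 <- table(hexes)
      tab[names(t2)] <- tab[names(t2)] + as.numeric(t2)
    }
    tab / sum(tab)
  }
  list(coding = count_set(coding_seqs), noncoding = count_set(noncoding_seqs))
}

#' Default hexamer tables from reference codon usage
#'
#' Builds a coding hexamer table as the product of the frequencies of two
#' adjacent codons under a standard mammalian codon-usage table (stop codons
#' excluded), and a noncoding table as an i.i.d. nucleotide model with mild
#' AT enrichment (A = T = 0.3, C = G = 0.2), typical of noncoding
#' transcripts.
#'
#' @return list with `coding` and `noncoding` frequency vectors, as
#'   [train_hexamer()].
#' @export
default_hexamer_tables <- function() {
  usage <- .codon_usage
  usage[.stop_codons] <- 0
  usage <- usage / sum(usage)
  hx <- .all_hexamers()
  c1 <- substring(hx, 1L, 3L)
  c2 <- substring(hx, 4L, 6L)
  coding <- usage[c1] * usage[c2]
  # guard against exact zeros (hexamers containing a stop codon)
  coding <- coding + 1e-8
  coding <- setNames(coding / sum(coding), hx)
  p <- c(A = 0.3, C = 0.2, G = 0.2, T = 0.3)
  base_mat <- matrix(unlist(strsplit(hx, "", fixed = TRUE)),
                     ncol = 6L, byrow = TRUE)
  noncoding <- apply(base_mat, 1L, function(r) prod(p[r]))
  noncoding <- setNames(noncoding / sum(noncoding), hx)
  list(coding = coding, noncoding = noncoding)
}

# Mammalian codon usage (frequencies per thousand, human reference values;
# used both by the synthetic coding-sequence generator and the default
# hexamer tables).
.codon_usage <- local({
  u <- c(
    TTT = 17.6, TTC = 20.3, TTA = 7.7, TTG = 12.9,
    CTT = 13.2, CTC = 19.6, CTA = 7.2, CTG = 39.6,
    ATT = 16.0, ATC = 20.8, ATA = 7.5, ATG = 22.0,
    GTT = 11.0, GTC = 14.5, GTA = 7.1, GTG = 28.1,
    TCT = 15.2, TCC = 17.7, TCA = 12.2, TCG = 4.4,
    CCT = 17.5, CCC = 19.8, CCA = 16.9, CCG = 6.9,
    ACT = 13.1, ACC = 18.9, ACA = 15.1, ACG = 6.1,
    GCT = 18.4, GCC = 27.7, GCA = 15.8, GCG = 7.4,
    TAT = 12.2, TAC = 15.3, TAA = 1.0, TAG = 0.8,
    CAT = 10.9, CAC = 15.1, CAA = 12.3, CAG = 34.2,
    AAT = 17.0, AAC = 19.1, AAA = 24.4, AAG = 31.9,
    GAT = 21.8, GAC = 25.1, GAA = 29.0, GAG = 39.6,
    TGT = 10.6, TGC = 12.6, TGA = 1.6, TGG = 13.2,
    CGT = 4.5, CGC = 10.4, CGA = 6.2, CGG = 11.4,
    AGT = 12.1, AGC = 19.5, AGA = 12.2, AGG = 12.0,
    GGT = 10.8, GGC = 22.2, GGA = 16.5, GGG = 16.5)
  u / sum(u)
})

#' Hexamer usage score of the longest ORF
#'
#' Mean log2 ratio of coding to noncoding hexamer frequencies over the
#' in-frame hexamers of a transcript's longest ORF. Positive values indicate
#' coding-like hexamer usage; 0 is returned when the transcript has no ORF.
#'
#' @param seq a single DNA sequence (character).
#' @param tables hexamer tables from [train_hexamer()] or
#'   [default_hexamer_tables()].
#' @return mean in-frame log2 frequency ratio (bits).
#' @export
hexamer_score <- function(seq, tables = default_hexamer_tables()) {
  orf <- find_orf(seq)
  if (orf$length < 6L) return(0)
  s <- orf$orf_seq
  starts <- seq.int(1L, nchar(s) - 5L, by = 3L)
  hexes <- substring(s, starts, starts + 5L)
  hexes <- hexes[!grepl("[^ACGT]", hexes)]
  if (!length(hexes)) return(0)
  mean(log2(tables$coding[hexes] / tables$noncoding[hexes]))
}

#' Score coding potential of transcript sequences
#'
#' Computes all built-in coding-potential signals for each sequence:
#' longest-ORF length, Fickett TESTCODE statistic, in-frame hexamer log
#' ratio, and a composite logistic score combining the three on documented
#' default weights:
#' `composite = plogis(1.5 * (orf_length/300 - 1) + 3 * (fickett - 0.95)
#'  + 2 * hexamer)`.
#'
#' @param sequences named character vector (or `Biostrings::DNAStringSet`)
#'   of transcript sequences. Names are transcript ids.
#' @param hexamer_tables tables from [train_hexamer()]; defaults to
#'   [default_hexamer_tables()].
#' @param weights numeric vector `c(orf, fickett, hexamer)` of composite
#'   weights.
#' @return data.frame with columns `transcript_id`, `orf_length`, `fickett`,
#'   `hexamer`, `composite`.
#' @export
score_coding_potential <- function(sequences,
                                   hexamer_tables = default_hexamer_tables(),
                                   weights = c(orf = 1.5, fickett = 3,
                                               hexamer = 2)) {
  if (methods::is(sequences, "XStringSet"))
    sequences <- setNames(as.character(sequences), names(sequences))
  stopifnot(!is.null(names(sequences)), all(nzchar(names(sequences))))
  seqs <- toupper(sequences)
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad))
    stop("sequence with non-ACGTN characters: ",
         paste(head(names(seqs)[bad], 3), collapse = ", "))
  n_frac <- vapply(seqs, function(s)
    lengths(regmatches(s, gregexpr("N", s, fixed = TRUE))) / nchar(s),
    numeric(1))
  if (any(n_frac > 0.1))
    warning("N fraction > 0.1 for ",
            sum(n_frac > 0.1), " sequence(s); scores may be unreliable")
  orf_length <- vapply(seqs, function(s) find_orf(s)$length, numeric(1))
  fickett <- vapply(seqs, fickett_score, numeric(1))
  hexamer <- vapply(seqs, hexamer_score, numeric(1),
                    tables = hexamer_tables)
  lp <- weights[["orf"]] * (orf_length / 300 - 1) +
    weights[["fickett"]] * (fickett - 0.95) +
    weights[["hexamer"]] * hexamer
  data.frame(transcript_id = names(seqs),
             orf_length = unname(orf_length),
             fickett = unname(fickett),
             hexamer = unname(hexamer),
             composite = unname(plogis(lp)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Consensus noncoding call across predictors
#'
#' A transcript is called noncoding only if every enabled internal predictor
#' calls it noncoding (`orf_length < orf_thr`, `fickett < fickett_thr`,
#' `hexamer < hexamer_thr`, `composite < composite_thr`) and, when external
#' score tables are supplied, every external predictor also calls it
#' noncoding (score < 0). This strict intersection matches the standard
#' practice of requiring all coding-potential tools to agree. Transcripts
#' absent from an external table are conservatively treated as coding, with
#' a warning.
#'
#' @param scores data.frame from [score_coding_potential()].
#' @param thresholds named list of internal thresholds; set an entry to `NA`
#'   to disable that predictor.
#' @param external optional data.frame with `transcript_id` plus one numeric
#'   column per external predictor (negative = noncoding), as read by
#'   [read_table()] with `schema = "scores"`.
#' @return character vector of transcript ids called noncoding.
#' @export
consensus_call <- function(scores,
                           thresholds = list(orf = 300, fickett = 0.95,
                                             hexamer = 0, composite = 0.5),
                           external = NULL) {
  enabled <- !vapply(thresholds, function(x) is.null(x) || is.na(x),
                     logical(1))
  if (!any(enabled)) stop("at least one internal predictor must be enabled")
  ok <- rep(TRUE, nrow(scores))
  if (enabled[["orf"]]) ok <- ok & scores$orf_length < thresholds$orf
  if (enabled[["fickett"]]) ok <- ok & scores$fickett < thresholds$fickett
  if (enabled[["hexamer"]]) ok <- ok & scores$hexamer < thresholds$hexamer
  if (enabled[["composite"]])
    ok <- ok & scores$composite < thresholds$composite
  if (!is.null(external)) {
    stopifnot("transcript_id" %in% names(external))
    idx <- match(scores$transcript_id, external$transcript_id)
    if (anyNA(idx))
      warning(sum(is.na(idx)), " transcript(s) missing from external score",
              " table treated as coding")
    for (col in setdiff(names(external), "transcript_id")) {
      ext_ok <- external[[col]][idx] < 0
      ext_ok[is.na(ext_ok)] <- FALSE
      ok <- ok & ext_ok
    }
  }
  scores$transcript_id[ok]
}
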