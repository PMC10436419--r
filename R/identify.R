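## lncRNA identification: the filter cascade from assembled transcripts to a
## classified catalog. Filters are monotone (output is always a subset of
## input) and the final classification partitions the catalog.

#' Basic structural/expression filter
#'
#' Keeps transcripts with `exon_count >= min_exons`, `length >= min_length`
#' and maximum per-sample read count `>= min_count`. Transcripts whose
#' assembly class code is `'='` and whose matched reference transcript is
#' annotated with biotype `"lncRNA"` bypass the exon filter: single-exon
#' known lncRNAs are legitimate catalog members, while single-exon novel
#' transcripts are unreliable assembly artifacts.
#'
#' @param transcripts transcript data.frame (see [read_gtf()]).
#' @param counts integer matrix of per-sample read counts, rownames =
#'   transcript ids. Transcripts absent from the matrix count as zero.
#' @param min_exons,min_length,min_count filter thresholds.
#' @param known_lnc_ids transcript ids allowed to bypass the exon filter.
#' @return the filtered transcript data.frame.
#' @export
basic_filter <- function(transcripts, counts, min_exons = 2,
                         min_length = 200, min_count = 1,
                         known_lnc_ids = NULL) {
  max_count <- rep(0, nrow(transcripts))
  idx <- match(transcripts$transcript_id, rownames(counts))
  has <- !is.na(idx)
  if (any(has))
    max_count[has] <- apply(counts[idx[has], , drop = FALSE], 1L, max)
  exon_ok <- transcripts$exon_count >= min_exons |
    transcripts$transcript_id %in% known_lnc_ids
  keep <- exon_ok & transcripts$length >= min_length & max_count >= min_count
  out <- transcripts[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Partition transcripts by assembly class code
#'
#' Novel lncRNA candidates are transcripts with class code in `allowed`
#' (defaults: `'i'` intronic, `'u'` intergenic, `'x'` exonic antisense).
#' Transcripts with class code `'='` are routed to the known-lncRNA check:
#' they are known lncRNAs when their matched reference transcript
#' (`cmp_ref`) carries biotype `"lncRNA"`. Everything else is discarded,
#' with per-code discard counts reported.
#'
#' @param transcripts transcript data.frame with `class_code` populated.
#' @param reference reference `AnnotationBundle` used to resolve `'='`
#'   matches to reference biotypes (optional; without it no transcript can
#'   be called a known lncRNA).
#' @param allowed class codes admitted as novel candidates.
#' @return list with `novel`, `known` (data.frames), and `discarded`
#'   (named integer vector of discard counts per class code).
#' @export
class_code_filter <- function(transcripts, reference = NULL,
                              allowed = c("i", "u", "x")) {
  cc <- transcripts$class_code
  cc[is.na(cc)] <- "unknown"
  is_novel <- cc %in% allowed
  is_eq <- cc == "="
  known_ok <- rep(FALSE, nrow(transcripts))
  if (!is.null(reference) && any(is_eq)) {
    ref_bio <- setNames(reference$transcripts$biotype,
                        reference$transcripts$transcript_id)
    known_ok <- is_eq & !is.na(transcripts$cmp_ref) &
      ref_bio[transcripts$cmp_ref] %in% "lncRNA"
  }
  discarded_codes <- cc[!(is_novel | known_ok)]
  unknown_codes <- setdiff(unique(cc), c(allowed, "="))
  if (length(unknown_codes))
    .log("class codes discarded: %s",
         paste(sort(unknown_codes), collapse = " "))
  list(novel = .reset_rows(transcripts[is_novel, , drop = FALSE]),
       known = .reset_rows(transcripts[known_ok, , drop = FALSE]),
       discarded = table(discarded_codes))
}

.reset_rows <- function(df) { rownames(df) <- NULL; df }

#' Classify lncRNA candidates into positional categories
#'
#' Maps assembly class codes to the standard lncRNA categories:
#' `'u'` to lincRNA (intergenic), `'i'` to ilncRNA (intronic), `'x'` to
#' lncNAT (antisense), and reference-matched transcripts to `known`. The
#' categories partition the catalog; `novel` is `TRUE` except for `known`.
#'
#' @param novel data.frame of consensus-passed novel candidates.
#' @param known data.frame of known lncRNAs (class `'='` matched to a
#'   reference lncRNA).
#' @return data.frame: the input rows plus `category` and `novel` columns.
#' @export
classify_lncrna <- function(novel, known = NULL) {
  map <- c(u = "lincRNA", i = "ilncRNA", x = "lncNAT")
  novel$category <- unname(map[novel$class_code])
  if (anyNA(novel$category))
    stop("novel candidate with class code outside i/u/x")
  novel$novel <- TRUE
  if (!is.null(known) && nrow(known)) {
    known$category <- "known"
    known$novel <- FALSE
    out <- rbind(novel, known)
  } else out <- novel
  .reset_rows(out)
}

#' Identify the lncRNA catalog from assembly, reference, sequences, counts
#'
#' Runs the full identification cascade: basic structural/expression filter,
#' class-code partition, coding-potential consensus on the novel candidates
#' (known lncRNAs are accepted on the strength of their reference
#' annotation), and positional classification.
#'
#' @param assembly assembly `AnnotationBundle`.
#' @param reference reference `AnnotationBundle`.
#' @param sequences named character vector of transcript sequences.
#' @param counts counts matrix (transcripts x samples).
#' @param min_exons,min_length,min_count see [basic_filter()].
#' @param thresholds consensus thresholds, see [consensus_call()].
#' @param hexamer_tables see [score_coding_potential()].
#' @param external optional external predictor score table.
#' @return list with `catalog` (classified lncRNA records), `scores`
#'   (coding-potential scores of the novel candidates), and `filtered`
#'   (transcripts surviving the basic filter).
#' @export
identify_lncrnas <- function(assembly, reference, sequences, counts,
                             min_exons = 2, min_length = 200, min_count = 1,
                             thresholds = list(orf = 300, fickett = 0.95,
                                               hexamer = 0, composite = 0.5),
                             hexamer_tables = default_hexamer_tables(),
                             external = NULL) {
  tx <- assembly$transcripts
  ref_lnc <- reference$transcripts$transcript_id[
    reference$transcripts$biotype %in% "lncRNA"]
  known_eq <- tx$transcript_id[tx$class_code %in% "=" &
                                 tx$cmp_ref %in% ref_lnc]
  filtered <- basic_filter(tx, counts, min_exons, min_length, min_count,
                           known_lnc_ids = known_eq)
  parts <- class_code_filter(filtered, reference)
  novel <- parts$novel
  if (nrow(novel)) {
    seqs <- sequences[novel$transcript_id]
    if (anyNA(seqs) || is.null(names(seqs)))
      stop("missing sequences for ",
           sum(is.na(seqs)), " novel candidate(s)")
    scores <- score_coding_potential(seqs, hexamer_tables)
    nc_ids <- consensus_call(scores, thresholds, external)
    novel <- novel[novel$transcript_id %in% nc_ids, , drop = FALSE]
  } else {
    scores <- data.frame(transcript_id = character(), orf_length = numeric(),
                         fickett = numeric(), hexamer = numeric(),
                         composite = numeric(), stringsAsFactors = FALSE)
  }
  catalog <- classify_lncrna(.reset_rows(novel), parts$known)
  list(catalog = catalog, scores = scores, filtered = filtered)
}

#' Summary feature report of a lncRNA catalog
#'
#' @param catalog classified catalog from [classify_lncrna()].
#' @param length_breaks bin edges for transcript length (nt).
#' @return list of summary tables: `exon_hist` (exon-count histogram),
#'   `length_bins` (length distribution), `per_chrom` (per-chromosome
#'   counts), `novelty` (novel/known split), `category` (category counts).
#'   All count tables sum to the catalog size. Empty catalog gives empty
#'   tables.
#' @export
feature_report <- function(catalog, length_breaks = c(200, 1500, Inf)) {
  if (!nrow(catalog)) {
    return(list(exon_hist = table(integer()),
                length_bins = table(character()),
                per_chrom = table(character()),
                novelty = table(logical()),
                category = table(character())))
  }
  breaks <- c(length_breaks[1] - 1, length_breaks[-1])
  lab <- paste0("[", head(length_breaks, -1), ",", length_breaks[-1], "]")
  lab[-1] <- sub("^\\[", "(", lab[-1])
  bins <- cut(catalog$length, breaks = breaks, labels = lab)
  list(exon_hist = table(exons = catalog$exon_count),
       length_bins = table(length = bins, useNA = "ifany"),
       per_chrom = table(chrom = catalog$chrom),
       novelty = table(novel = catalog$novel),
       category = table(category = catalog$category))
}
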