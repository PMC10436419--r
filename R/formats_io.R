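## formats_io: readers/writers for every external format the pipeline touches.
## All genomic coordinates are 1-based inclusive internally; GTF already is,
## so no conversion is needed on that path.

#' Read a GTF annotation into an AnnotationBundle
#'
#' Parses a 9-column GTF file into the package's annotation container. Two
#' dialects are understood: `source = "reference"` (Ensembl-style, carrying
#' `gene_biotype` / `transcript_biotype` attributes) and `source = "assembly"`
#' (StringTie/gffcompare-style, carrying `class_code` and optionally
#' `cmp_ref` attributes). Chromosome names are normalized by stripping a
#' leading `"chr"` prefix.
#'
#' @param path path to a GTF file.
#' @param source `"reference"` or `"assembly"`; controls which attributes are
#'   harvested.
#' @return an object of class `AnnotationBundle`: a list with elements
#'   \describe{
#'     \item{transcripts}{data.frame with one row per transcript:
#'       `transcript_id`, `gene_id`, `chrom`, `strand`, `start`, `end`,
#'       `length` (sum of exon widths), `exon_count`, `class_code`
#'       (`"unknown"` when absent on assembly records), `cmp_ref`,
#'       `biotype`.}
#'     \item{exons}{data.frame of exon intervals (`transcript_id`, `chrom`,
#'       `strand`, `start`, `end`), sorted within transcript.}
#'     \item{genes}{data.frame `gene_id`, `chrom`, `start`, `end`, `strand`,
#'       `biotype` (span of member transcripts when no explicit gene rows
#'       exist).}
#'     \item{source}{the dialect the file was read as.}
#'   }
#' @export
read_gtf <- function(path, source = c("reference", "assembly")) {
  source <- match.arg(source)
  stopifnot(file.exists(path))
  n_records <- .validate_gtf_lines(path)
  if (n_records == 0L) {
    return(.new_annotation_bundle(
      transcripts = .empty_transcripts(), exons = .empty_exons(),
      genes = .empty_genes(), source = source))
  }
  gr <- rtracklayer::import(path, format = "gtf")
  df <- as.data.frame(gr, stringsAsFactors = FALSE)
  df$seqnames <- sub("^chr", "", as.character(df$seqnames))
  df$strand <- as.character(df$strand)

  ex <- df[df$type == "exon", , drop = FALSE]
  if (nrow(ex) == 0L) {
    return(.new_annotation_bundle(
      transcripts = .empty_transcripts(), exons = .empty_exons(),
      genes = .empty_genes(), source = source))
  }
  if (is.null(ex$transcript_id) || anyNA(ex$transcript_id))
    stop("GTF exon records without transcript_id in ", path)

  exons <- data.frame(
    transcript_id = ex$transcript_id,
    chrom = ex$seqnames, strand = ex$strand,
    start = ex$start, end = ex$end,
    stringsAsFactors = FALSE)
  exons <- exons[order(exons$transcript_id, exons$start), , drop = FALSE]
  rownames(exons) <- NULL

  grab <- function(col) if (!is.null(ex[[col]])) ex[[col]] else rep(NA_character_, nrow(ex))
  first_per_tx <- function(x, id) vapply(split(x, id), function(v) {
    v <- v[!is.na(v)]
    if (length(v)) v[[1L]] else NA_character_
  }, character(1))

  id <- exons$transcript_id
  # consistency: one chrom and strand per transcript
  n_chrom <- vapply(split(exons$chrom, id), function(v) length(unique(v)), integer(1))
  n_str <- vapply(split(exons$strand, id), function(v) length(unique(v)), integer(1))
  bad <- names(n_chrom)[n_chrom > 1L | n_str > 1L]
  if (length(bad))
    stop("conflicting chrom/strand for transcript(s): ",
         paste(head(bad, 5), collapse = ", "))

  ex_o <- ex[order(ex$transcript_id, ex$start), , drop = FALSE]
  id_o <- ex_o$transcript_id
  grab_o <- function(col) if (!is.null(ex_o[[col]])) ex_o[[col]] else rep(NA_character_, nrow(ex_o))

  tx <- data.frame(
    transcript_id = names(split(seq_along(id_o), id_o)),
    stringsAsFactors = FALSE)
  by_tx <- split(seq_len(nrow(ex_o)), id_o)
  tx$gene_id <- first_per_tx(grab_o("gene_id"), id_o)[tx$transcript_id]
  tx$chrom <- vapply(by_tx, function(i) ex_o$seqnames[i[1L]], character(1))
  tx$strand <- vapply(by_tx, function(i) ex_o$strand[i[1L]], character(1))
  tx$start <- vapply(by_tx, function(i) min(ex_o$start[i]), numeric(1))
  tx$end <- vapply(by_tx, function(i) max(ex_o$end[i]), numeric(1))
  tx$length <- vapply(by_tx, function(i) sum(ex_o$end[i] - ex_o$start[i] + 1), numeric(1))
  tx$exon_count <- lengths(by_tx)

  if (source == "assembly") {
    cc <- first_per_tx(grab_o("class_code"), id_o)[tx$transcript_id]
    cc[is.na(cc)] <- "unknown"
    tx$class_code <- cc
    tx$cmp_ref <- first_per_tx(grab_o("cmp_ref"), id_o)[tx$transcript_id]
    tx$biotype <- NA_character_
  } else {
    tx$class_code <- NA_character_
    tx$cmp_ref <- NA_character_
    bio <- first_per_tx(grab_o("transcript_biotype"), id_o)
    gbio <- first_per_tx(grab_o("gene_biotype"), id_o)
    bio[is.na(bio)] <- gbio[is.na(bio)]
    tx$biotype <- bio[tx$transcript_id]
  }
  rownames(tx) <- NULL

  # gene table: explicit gene rows if present, else span of member transcripts
  gdf <- df[df$type == "gene", , drop = FALSE]
  if (nrow(gdf) > 0L && !is.null(gdf$gene_id)) {
    genes <- data.frame(
      gene_id = gdf$gene_id, chrom = gdf$seqnames,
      start = gdf$start, end = gdf$end, strand = gdf$strand,
      biotype = if (!is.null(gdf$gene_biotype)) gdf$gene_biotype else NA_character_,
      stringsAsFactors = FALSE)
  } else {
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
      }, character(1)),
      stringsAsFactors = FALSE)
  }
  rownames(genes) <- NULL

  .new_annotation_bundle(transcripts = tx, exons = exons, genes = genes,
                         source = source)
}

.validate_gtf_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^#", lines) & nzchar(lines)
  nf <- vapply(strsplit(lines[keep], "\t", fixed = TRUE), length, integer(1))
  if (any(nf < 9L)) {
    lineno <- which(keep)[which(nf < 9L)[1L]]
    stop("malformed GTF line ", lineno, " in ", path,
         ": expected 9 tab-separated columns, found ", nf[which(nf < 9L)[1L]])
  }
  sum(keep)
}

.empty_transcripts <- function() {
  data.frame(transcript_id = character(), gene_id = character(),
             chrom = character(), strand = character(),
             start = numeric(), end = numeric(), length = numeric(),
             exon_count = integer(), class_code = character(),
             cmp_ref = character(), biotype = character(),
             stringsAsFactors = FALSE)
}
.empty_exons <- function() {
  data.frame(transcript_id = character(), chrom = character(),
             strand = character(), start = numeric(), end = numeric(),
             stringsAsFactors = FALSE)
}
.empty_genes <- function() {
  data.frame(gene_id = character(), chrom = character(), start = numeric(),
             end = numeric(), strand = character(), biotype = character(),
             stringsAsFactors = FALSE)
}

.new_annotation_bundle <- function(transcripts, exons, genes, source) {
  structure(list(transcripts = transcripts, exons = exons, genes = genes,
                 source = source),
            class = "AnnotationBundle")
}

#' @export
print.AnnotationBundle <- function(x, ...) {
  cat("AnnotationBundle (", x$source, "): ",
      nrow(x$transcripts), " transcripts, ",
      nrow(x$genes), " genes, ", nrow(x$exons), " exons\n", sep = "")
  invisible(x)
}

#' Read and validate a typed pipeline table
#'
#' One entry point for the tabular inputs. `schema` selects the expected
#' columns and the validation applied:
#' \describe{
#'   \item{counts}{TSV, first column feature ids, remaining columns one per
#'     sample; values coerced to nonnegative integers. Features must be in
#'     rows; the orientation is never guessed.}
#'   \item{samples}{columns `sample_id`, `group` (one of SF, SC, HF, HC),
#'     `scc` (somatic cell count, x1000 cells/mL, nonnegative).}
#'   \item{qtl}{columns `chrom`, `start`, `end`, `trait`, `qtl_id`.}
#'   \item{gwas}{columns `chrom`, `pos`, `trait`, `pvalue` with
#'     p-values in (0, 1].}
#'   \item{gmt}{standard GMT (term, description, member genes...); terms
#'     with zero members are retained with a warning.}
#'   \item{scores}{column `transcript_id` plus one numeric column per
#'     external coding-potential predictor.}
#' }
#'
#' @param path file path.
#' @param schema one of `"counts"`, `"samples"`, `"qtl"`, `"gwas"`, `"gmt"`,
#'   `"scores"`.
#' @return counts: integer matrix (features x samples); gmt: named list of
#'   character vectors with a `description` attribute per element; others:
#'   validated data.frame.
#' @export
read_table <- function(path, schema = c("counts", "samples", "qtl", "gwas",
                                        "gmt", "scores")) {
  schema <- match.arg(schema)
  stopifnot(file.exists(path))
  if (schema == "gmt") return(.read_gmt(path))
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  switch(schema,
    counts = .validate_counts(df, path),
    samples = .validate_samples(df, path),
    qtl = .validate_qtl(df, path),
    gwas = .validate_gwas(df, path),
    scores = .validate_scores(df, path))
}

.need_cols <- function(df, cols, path) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop("table ", path, " is missing mandatory column(s): ",
         paste(miss, collapse = ", "))
}

.validate_counts <- function(df, path) {
  if (ncol(df) < 2L) stop("counts table ", path, " needs id column + samples")
  ids <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  bad <- which(!is.finite(m) | m < 0, arr.ind = TRUE)
  if (nrow(bad)) {
    stop("negative or non-numeric count at feature '", ids[bad[1, 1]],
         "', sample '", colnames(m)[bad[1, 2]], "' in ", path)
  }
  if (any(abs(m - round(m)) > 1e-8))
    stop("non-integer counts in ", path)
  m <- round(m)
  storage.mode(m) <- "integer"
  rownames(m) <- ids
  m
}

.validate_samples <- function(df, path) {
  .need_cols(df, c("sample_id", "group", "scc"), path)
  ok <- df$group %in% c("SF", "SC", "HF", "HC")
  if (!all(ok))
    stop("invalid group label '", df$group[which(!ok)[1]], "' for sample '",
         df$sample_id[which(!ok)[1]], "' in ", path)
  df$scc <- as.numeric(df$scc)
  if (any(!is.finite(df$scc) | df$scc < 0)) {
    i <- which(!is.finite(df$scc) | df$scc < 0)[1]
    stop("invalid scc for sample '", df$sample_id[i], "' in ", path)
  }
  df
}

.validate_qtl <- function(df, path) {
  .need_cols(df, c("chrom", "start", "end", "trait", "qtl_id"), path)
  df$chrom <- sub("^chr", "", as.character(df$chrom))
  for (col in c("start", "end")) {
    df[[col]] <- as.numeric(df[[col]])
    if (any(!is.finite(df[[col]]) | df[[col]] < 1)) {
      i <- which(!is.finite(df[[col]]) | df[[col]] < 1)[1]
      stop("invalid ", col, " in row ", i, " of ", path)
    }
  }
  if (any(df$start > df$end))
    stop("QTL with start > end in row ", which(df$start > df$end)[1],
         " of ", path)
  df
}

.validate_gwas <- function(df, path) {
  .need_cols(df, c("chrom", "pos", "trait", "pvalue"), path)
  df$chrom <- sub("^chr", "", as.character(df$chrom))
  df$pos <- as.numeric(df$pos)
  if (any(!is.finite(df$pos) | df$pos < 1)) {
    i <- which(!is.finite(df$pos) | df$pos < 1)[1]
    stop("invalid pos in row ", i, " of ", path)
  }
  df$pvalue <- as.numeric(df$pvalue)
  bad <- !is.finite(df$pvalue) | df$pvalue <= 0 | df$pvalue > 1
  if (any(bad))
    stop("p-value outside (0,1] in row ", which(bad)[1], " of ", path)
  df
}

.validate_scores <- function(df, path) {
  .need_cols(df, "transcript_id", path)
  num <- setdiff(names(df), "transcript_id")
  if (!length(num)) stop("scores table ", path, " has no predictor columns")
  for (col in num) df[[col]] <- as.numeric(df[[col]])
  df
}

# GMT is line-oriented: term \t description \t members... ; kept in-house to
# preserve the description field and zero-member terms.
.read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- vapply(parts, length, integer(1)) < 2L
  if (any(short))
    stop("malformed GMT line ", which(short)[1], " in ", path)
  terms <- vapply(parts, `[[`, character(1), 1L)
  out <- lapply(parts, function(p) {
    members <- if (length(p) > 2L) unique(p[-c(1L, 2L)]) else character()
    attr(members, "description") <- p[[2L]]
    members
  })
  names(out) <- terms
  empty <- lengths(out) == 0L
  if (any(empty)) {
    warning("GMT term(s) with zero members retained: ",
            paste(head(terms[empty], 5), collapse = ", "))
  }
  out
}

#' Write stage outputs and a JSON run manifest
#'
#' Writes one TSV per result table and a `manifest.json` recording the run
#' parameters and the md5 checksum of every file written. Re-running with
#' the same tables and parameters produces byte-identical output.
#'
#' @param tables named list of data.frames (or matrices with rownames).
#' @param outdir output directory, created if needed.
#' @param params named list of run parameters echoed into the manifest.
#' @return (invisibly) the manifest as a list.
#' @export
write_results <- function(tables, outdir, params = list()) {
  stopifnot(is.list(tables), !is.null(names(tables)), all(nzchar(names(tables))))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outdir)) stop("cannot create output directory ", outdir)
  files <- character()
  for (nm in names(tables)) {
    tab <- tables[[nm]]
    if (is.matrix(tab)) {
      tab <- data.frame(feature_id = rownames(tab), as.data.frame(tab),
                        check.names = FALSE, stringsAsFactors = FALSE)
    }
    fp <- file.path(outdir, paste0(nm, ".tsv"))
    ok <- tryCatch({
      write.table(tab, fp, sep = "\t", quote = FALSE, row.names = FALSE)
      TRUE
    }, error = function(e) FALSE)
    if (!ok) stop("cannot write ", fp)
    files <- c(files, fp)
  }
  manifest <- list(
    package = "lncmast",
    parameters = params,
    files = lapply(setNames(files, basename(files)), function(f)
      list(md5 = unname(md5sum(f)), rows = length(readLines(f)) - 1L)))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
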