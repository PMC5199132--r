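#' @keywords internal
#' @importFrom stats median sd runif setNames ave
#' @importFrom utils head read.delim write.table
"_PACKAGE"

## Closed vocabularies of the relational model. Gene types follow the
## NCBI Gene "Gene_Type" field; RefSeq statuses are the NCBI curation tiers.

#' Closed vocabulary of gene types
#' @export
GENE_TYPES <- c("protein-coding", "pseudo", "ncRNA", "snoRNA", "snRNA",
                "rRNA", "tRNA", "other", "unknown")

#' Closed vocabulary of RefSeq curation statuses
#' @export
REFSEQ_STATUSES <- c("REVIEWED", "VALIDATED", "PROVISIONAL", "PREDICTED",
                     "INFERRED", "MODEL", "none")

#' RefSeq RNA accession prefixes
#' @export
ACCESSION_PREFIXES <- c("NM_", "NR_", "XM_", "XR_")

#' Construct a table of genomic intervals
#'
#' Coordinates are 1-based and inclusive throughout the package (the GFF3
#' convention), so an interval of a single base has `start == end` and
#' length 1. Strand is `"+"`, `"-"`, or `"."` for unknown.
#'
#' @param chrom chromosome name(s)
#' @param start,end 1-based inclusive positions (bp)
#' @param strand strand character(s), recycled
#' @return a data.frame with columns `chrom`, `start`, `end`, `strand`
#' @examples
#' genomic_interval("chr1", 10, 12)
#' @export
genomic_interval <- function(chrom, start, end, strand = "+") {
  iv <- data.frame(chrom = as.character(chrom),
                   start = as.integer(start),
                   end = as.integer(end),
                   strand = as.character(strand),
                   stringsAsFactors = FALSE)
  bad <- !iv$strand %in% c("+", "-", ".")
  if (any(bad)) stop("invalid strand value(s): ",
                     paste(unique(iv$strand[bad]), collapse = ", "))
  iv
}

#' Length of genomic intervals in bp
#'
#' @param iv a data.frame with `start` and `end` columns (1-based inclusive)
#' @return integer vector of lengths, `end - start + 1`
#' @examples
#' interval_length(genomic_interval("chr1", 10, 12))  # 3
#' @export
interval_length <- function(iv) {
  stopifnot(is.data.frame(iv), all(c("start", "end") %in% names(iv)))
  bad <- which(iv$start > iv$end | iv$start < 1L)
  if (length(bad)) {
    stop("invalid interval(s) (start > end or start < 1) at row(s) ",
         paste(bad, collapse = ", "), ": ",
         paste0("[", iv$start[bad], ",", iv$end[bad], "]", collapse = " "))
  }
  as.integer(iv$end - iv$start + 1L)
}

## internal: empty interval frame
empty_intervals <- function() {
  data.frame(chrom = character(), start = integer(), end = integer(),
             strand = character(), stringsAsFactors = FALSE)
}

#' Accession prefix of RefSeq RNA accessions
#'
#' @param accession character vector of accessions
#' @return the matched prefix (`"NM_"`, `"NR_"`, `"XM_"`, `"XR_"`) or `NA`
#' @export
accession_prefix <- function(accession) {
  m <- regmatches(accession, regexpr("^[NX][MR]_", accession))
  out <- rep(NA_character_, length(accession))
  out[regexpr("^[NX][MR]_", accession) == 1L] <- m
  out
}

#' Validate a transcript's structure
#'
#' Checks the structural contract of a transcript: exons on one chromosome
#' and strand, pairwise non-overlapping, listed in transcription order
#' (ascending genomic start on the plus strand, descending on the minus
#' strand), CDS fully contained in the exons, and accession-prefix
#' consistency (`NM_` implies a CDS, `NR_` implies none). Violations are
#' returned as data, not thrown.
#'
#' @param exons interval data.frame in transcription order
#' @param cds_segments interval data.frame of CDS segments (or `NULL`)
#' @param accession optional accession used for the prefix contract
#' @return character vector of violation descriptions; empty when valid
#' @export
validate_transcript <- function(exons, cds_segments = NULL, accession = NA) {
  v <- character()
  n <- nrow(exons)
  if (n == 0L) return("transcript has no exons")
  if (any(exons$start > exons$end | exons$start < 1L))
    v <- c(v, "invalid exon interval (start > end or start < 1)")
  if (length(unique(exons$chrom)) > 1L)
    v <- c(v, "exons on multiple chromosomes")
  if (length(unique(exons$strand)) > 1L)
    v <- c(v, "exons on multiple strands")
  if (length(v) == 0L && n > 1L) {
    g <- exons[order(exons$start), , drop = FALSE]
    if (any(g$end[-n] >= g$start[-1]))
      v <- c(v, paste0("overlapping exons (",
                       paste0("[", g$start, ",", g$end, "]", collapse = " "),
                       ")"))
    want <- if (exons$strand[1] == "-") rev(order(exons$start)) else order(exons$start)
    if (!identical(want, seq_len(n)))
      v <- c(v, "exons not in transcription order")
  }
  if (!is.null(cds_segments) && nrow(cds_segments) > 0L) {
    if (any(cds_segments$start > cds_segments$end))
      v <- c(v, "invalid CDS interval (start > end)")
    else {
      inside <- vapply(seq_len(nrow(cds_segments)), function(i) {
        any(exons$start <= cds_segments$start[i] & exons$end >= cds_segments$end[i])
      }, logical(1))
      if (!all(inside))
        v <- c(v, paste0("CDS segment outside exons ([",
                         paste0(cds_segments$start[!inside], ",",
                                cds_segments$end[!inside], collapse = "] ["),
                         "])"))
    }
  }
  pref <- if (is.na(accession)) NA_character_ else accession_prefix(accession)
  has_cds <- !is.null(cds_segments) && nrow(cds_segments) > 0L
  if (!is.na(pref)) {
    if (pref == "NM_" && !has_cds) v <- c(v, "NM_ accession without CDS")
    if (pref == "NR_" && has_cds)  v <- c(v, "NR_ accession with CDS")
  }
  v
}

## canonical sort used everywhere so that round-trips compare equal
sort_genes <- function(genes) {
  genes[order(genes$gene_id), , drop = FALSE]
}
sort_transcripts <- function(tx) {
  tx[order(tx$gene_id, tx$accession), , drop = FALSE]
}
sort_rows <- function(rows) {
  rows[order(rows$gene_id, rows$accession, rows$exon_index), , drop = FALSE]
}

empty_genes <- function() {
  data.frame(gene_id = character(), symbol = character(),
             gene_type = character(), chrom = character(),
             strand = character(), refseq_status = character(),
             in_current_annotation = logical(),
             span_start = integer(), span_end = integer(),
             stringsAsFactors = FALSE)
}
empty_transcripts <- function() {
  data.frame(accession = character(), gene_id = character(),
             transcript_status = character(), stringsAsFactors = FALSE)
}
empty_rows <- function() {
  data.frame(gene_id = character(), accession = character(),
             exon_index = integer(), chrom = character(), strand = character(),
             exon_start = integer(), exon_end = integer(),
             cds_start = integer(), cds_end = integer(),
             intron_start = integer(), intron_end = integer(),
             exon_seq = character(), coding_seq = character(),
             intron_seq = character(), stringsAsFactors = FALSE)
}
empty_ontology <- function() {
  data.frame(gene_id = character(), go_id = character(), go_name = character(),
             aspect = character(), stringsAsFactors = FALSE)
}

#' Assemble an annotation set
#'
#' The in-memory relational model: a `genes` table, a `transcripts` table, a
#' `rows` table holding one record per exon of each transcript (carrying the
#' coding part of the exon and the downstream intron, if any), and an
#' optional gene-ontology table. Referential integrity is enforced: every
#' transcript's `gene_id` must exist in `genes` and every row's `accession`
#' in `transcripts`. Tables are stored in a canonical sort order
#' (gene_id, accession, exon_index) so that equal sets compare equal.
#'
#' @param genes data.frame: gene_id, symbol, gene_type, chrom, strand,
#'   refseq_status, in_current_annotation, span_start, span_end
#' @param transcripts data.frame: accession, gene_id, transcript_status
#' @param rows data.frame: the exon-level expansion (see [exon_rows()])
#' @param ontology data.frame: gene_id, go_id, go_name, aspect
#' @param provenance free-text description of the data source
#' @return an object of class `annotation_set`
#' @export
annotation_set <- function(genes = empty_genes(),
                           transcripts = empty_transcripts(),
                           rows = empty_rows(),
                           ontology = empty_ontology(),
                           provenance = "") {
  genes$in_current_annotation <- as.logical(genes$in_current_annotation)
  for (col in c("span_start", "span_end"))
    genes[[col]] <- as.integer(genes[[col]])
  for (col in c("exon_index", "exon_start", "exon_end", "cds_start",
                "cds_end", "intron_start", "intron_end"))
    if (col %in% names(rows)) rows[[col]] <- as.integer(rows[[col]])
  for (col in c("exon_seq", "coding_seq", "intron_seq"))
    if (!col %in% names(rows)) rows[[col]] <- rep(NA_character_, nrow(rows))

  if (anyDuplicated(genes$gene_id))
    stop("duplicated gene_id in genes table")
  if (anyDuplicated(transcripts$accession))
    stop("duplicated accession in transcripts table")
  bad_type <- setdiff(unique(genes$gene_type), GENE_TYPES)
  if (length(bad_type))
    stop("unknown gene_type value(s): ", paste(bad_type, collapse = ", "))
  miss_g <- setdiff(transcripts$gene_id, genes$gene_id)
  if (length(miss_g))
    stop("transcripts reference unknown gene_id(s): ",
         paste(utils::head(miss_g, 5), collapse = ", "))
  miss_t <- setdiff(rows$accession, transcripts$accession)
  if (length(miss_t))
    stop("rows reference unknown accession(s): ",
         paste(utils::head(miss_t, 5), collapse = ", "))
  no_tx <- setdiff(genes$gene_id, transcripts$gene_id)
  no_span <- no_tx[is.na(genes$span_start[match(no_tx, genes$gene_id)])]
  if (length(no_span))
    warning("gene(s) without transcripts and without an annotated span: ",
            paste(utils::head(no_span, 5), collapse = ", "))

  genes <- sort_genes(genes)
  transcripts <- sort_transcripts(transcripts)
  rows <- sort_rows(rows)
  rownames(genes) <- rownames(transcripts) <- rownames(rows) <- NULL
  if (nrow(ontology)) rownames(ontology) <- NULL
  structure(list(genes = genes, transcripts = transcripts, rows = rows,
                 ontology = ontology, provenance = provenance),
            class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat("annotation_set:", nrow(x$genes), "genes,",
      nrow(x$transcripts), "transcripts,",
      nrow(x$rows), "exon rows,",
      nrow(x$ontology), "ontology records\n")
  if (nzchar(x$provenance)) cat("provenance:", x$provenance, "\n")
  invisible(x)
}

#' Exon-level expansion of one transcript
#'
#' Builds the per-exon records of the `rows` table for a single transcript:
#' one row per exon in transcription order, carrying the coding part of the
#' exon (if any) and the downstream intron (present for every exon except
#' the transcription-last one). The transcript is validated first; any
#' structural violation is a hard error naming the transcript.
#'
#' @param gene_id,accession identifiers for the rows
#' @param exons interval data.frame in transcription order
#' @param cds_segments interval data.frame of CDS segments (or `NULL`);
#'   either per-exon pieces or genomic spans, both are intersected with the
#'   exons
#' @return data.frame of exon rows
#' @export
exon_rows <- function(gene_id, accession, exons, cds_segments = NULL) {
  viol <- validate_transcript(exons, cds_segments, accession)
  if (length(viol))
    stop("invalid transcript ", accession, ": ", paste(viol, collapse = "; "))
  n <- nrow(exons)
  introns <- infer_introns(exons, accession)
  parts <- coding_exon_intervals(exons, cds_segments, accession)
  data.frame(gene_id = gene_id, accession = accession,
             exon_index = seq_len(n),
             chrom = exons$chrom, strand = exons$strand,
             exon_start = exons$start, exon_end = exons$end,
             cds_start = parts$start, cds_end = parts$end,
             intron_start = c(introns$start, NA_integer_)[seq_len(n)],
             intron_end = c(introns$end, NA_integer_)[seq_len(n)],
             exon_seq = NA_character_, coding_seq = NA_character_,
             intron_seq = NA_character_, stringsAsFactors = FALSE)
}
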