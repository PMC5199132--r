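## I/O: GFF3 and the native three-table tab-delimited dialect, chromosome
## FASTA, and TSV export of the derived feature tables. GFF3 parsing is
## delegated to rtracklayer::readGFF and FASTA to Biostrings; the relational
## assembly on top of them is done here.

NATIVE_GENE_SUMMARY_COLS <- c("gene_id", "symbol", "gene_type", "chrom",
                              "strand", "refseq_status",
                              "in_current_annotation", "span_start",
                              "span_end")
NATIVE_GENE_TABLE_COLS <- c("gene_id", "accession", "transcript_status",
                            "exon_index", "exon_start", "exon_end",
                            "cds_start", "cds_end", "intron_start",
                            "intron_end")
NATIVE_ONTOLOGY_COLS <- c("gene_id", "go_id", "go_name", "aspect")

#' Read chromosome sequences from FASTA
#'
#' Record IDs are taken as the first whitespace-delimited token of each
#' header. Sequences are uppercased on load (soft-masking is discarded:
#' the statistics are mask-agnostic).
#'
#' @param path FASTA file
#' @return a [genome_assembly()] with sequences and lengths
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(ids))
    stop("duplicate FASTA record id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (any(Biostrings::width(ss) == 0L))
    stop("empty FASTA record(s): ", paste(ids[Biostrings::width(ss) == 0L],
                                          collapse = ", "))
  seqs <- toupper(as.character(ss))
  names(seqs) <- ids
  genome_assembly(sequences = seqs)
}

#' Write chromosome sequences to FASTA
#'
#' @param asm a [genome_assembly()] with sequences
#' @param path output file
#' @return `path`, invisibly
#' @export
write_fasta <- function(asm, path) {
  stopifnot(inherits(asm, "genome_assembly"), !is.null(asm$sequences))
  ss <- Biostrings::DNAStringSet(asm$sequences)
  Biostrings::writeXStringSet(ss, path, width = 70L)
  invisible(path)
}

## internal: first Parent of each GFF3 feature (readGFF yields a list column)
first_parent <- function(p) {
  vapply(p, function(x) if (length(x)) as.character(x)[1] else NA_character_,
         character(1))
}

#' Read genome annotation from GFF3
#'
#' Expects the standard gene / mRNA-or-transcript / exon / CDS hierarchy
#' with `Parent` links. Gene type is taken from the `gene_biotype`
#' attribute (configurable), RefSeq statuses from `refseq_status`
#' (defaulting to `"none"` when absent), and the "in current annotation
#' release" flag from `in_current_annotation` (absent means `TRUE`).
#' Exons are normalized to transcription order regardless of file order;
#' features with unknown strand `"."` are kept but a warning is issued
#' since transcription order is ambiguous for them. Orphan `Parent`
#' references and CDS outside exons are hard errors.
#'
#' @param path GFF3 file
#' @param biotype_attr attribute carrying the gene type
#' @return an [annotation_set()]
#' @export
read_gff3 <- function(path, biotype_attr = "gene_biotype") {
  g <- rtracklayer::readGFF(path)
  g <- as.data.frame(g, stringsAsFactors = FALSE)
  g$seqid <- as.character(g$seqid)
  g$type <- as.character(g$type)
  g$strand <- as.character(g$strand)
  g$strand[is.na(g$strand) | g$strand == "*"] <- "."
  g$ID <- if ("ID" %in% names(g)) as.character(g$ID) else NA_character_
  g$parent1 <- if ("Parent" %in% names(g)) first_parent(g$Parent)
               else NA_character_
  get_attr <- function(df, col, default) {
    if (col %in% names(df)) {
      v <- as.character(df[[col]])
      v[is.na(v)] <- default
      v
    } else rep(default, nrow(df))
  }

  gg <- g[g$type == "gene", , drop = FALSE]
  tt <- g[g$type %in% c("mRNA", "transcript"), , drop = FALSE]
  ee <- g[g$type == "exon", , drop = FALSE]
  cc <- g[g$type == "CDS", , drop = FALSE]

  biotype <- get_attr(gg, biotype_attr, "unknown")
  biotype[biotype == "protein_coding"] <- "protein-coding"
  unknown_bt <- !biotype %in% GENE_TYPES
  if (any(unknown_bt)) {
    warning("unrecognized gene_biotype value(s) mapped to 'unknown': ",
            paste(unique(biotype[unknown_bt]), collapse = ", "))
    biotype[unknown_bt] <- "unknown"
  }
  genes <- data.frame(
    gene_id = gg$ID,
    symbol = get_attr(gg, "Name", NA_character_),
    gene_type = biotype,
    chrom = gg$seqid, strand = gg$strand,
    refseq_status = get_attr(gg, "refseq_status", "none"),
    in_current_annotation =
      get_attr(gg, "in_current_annotation", "true") != "false",
    span_start = as.integer(gg$start), span_end = as.integer(gg$end),
    stringsAsFactors = FALSE)
  genes$symbol[is.na(genes$symbol)] <- genes$gene_id[is.na(genes$symbol)]

  tx_acc <- get_attr(tt, "transcript_id", NA_character_)
  tx_acc[is.na(tx_acc)] <- tt$ID[is.na(tx_acc)]
  orphan_tx <- setdiff(tt$parent1, genes$gene_id)
  if (length(orphan_tx))
    stop("transcript(s) with orphan Parent reference(s): ",
         paste(orphan_tx, collapse = ", "))
  transcripts <- data.frame(
    accession = tx_acc, gene_id = tt$parent1,
    transcript_status = get_attr(tt, "refseq_status", "none"),
    stringsAsFactors = FALSE)
  tx_by_id <- stats::setNames(tx_acc, tt$ID)

  orphans <- setdiff(c(ee$parent1, cc$parent1), tt$ID)
  if (length(orphans))
    stop("exon/CDS feature(s) with orphan Parent reference(s): ",
         paste(unique(orphans), collapse = ", "))
  unknown_strand <- unique(tt$ID[tt$strand == "."])
  if (length(unknown_strand))
    warning("transcript(s) with unknown strand '.', exon order assumed ",
            "ascending: ", paste(unknown_strand, collapse = ", "))

  exons_by_tx <- split(ee, tx_by_id[ee$parent1])
  cds_by_tx <- split(cc, tx_by_id[cc$parent1])
  gene_of_tx <- stats::setNames(transcripts$gene_id, transcripts$accession)

  rows <- lapply(names(exons_by_tx), function(acc) {
    e <- exons_by_tx[[acc]]
    ex <- data.frame(chrom = e$seqid, start = as.integer(e$start),
                     end = as.integer(e$end), strand = e$strand,
                     stringsAsFactors = FALSE)
    ex <- ex[order(ex$start), , drop = FALSE]
    if (ex$strand[1] == "-") ex <- ex[rev(seq_len(nrow(ex))), , drop = FALSE]
    cd <- cds_by_tx[[acc]]
    cds <- if (is.null(cd) || nrow(cd) == 0L) NULL else
      data.frame(chrom = cd$seqid, start = as.integer(cd$start),
                 end = as.integer(cd$end), strand = cd$strand,
                 stringsAsFactors = FALSE)
    exon_rows(gene_of_tx[[acc]], acc, ex, cds)
  })
  rows <- if (length(rows)) do.call(rbind, rows) else empty_rows()

  annotation_set(genes = genes, transcripts = transcripts, rows = rows,
                 provenance = paste0("gff3:", basename(path)))
}

#' Write genome annotation as GFF3
#'
#' Emits the gene / mRNA-or-transcript / exon / CDS hierarchy in the
#' attribute dialect that [read_gff3()] reads back. CDS phase is computed
#' cumulatively over the coding exons in transcription order. Output is
#' deterministic for a given annotation set.
#'
#' @param x an `annotation_set`
#' @param path output file
#' @param asm optional [genome_assembly()] used for `##sequence-region`
#'   directives
#' @return `path`, invisibly
#' @export
write_gff3 <- function(x, path, asm = NULL) {
  stopifnot(inherits(x, "annotation_set"))
  esc <- function(s) gsub("([,;=&\t])", "-", s)
  lines <- "##gff-version 3"
  if (!is.null(asm) && length(asm$lengths))
    lines <- c(lines, paste("##sequence-region", names(asm$lengths), 1L,
                            asm$lengths))
  fmt <- function(seqid, type, start, end, strand, phase, attrs)
    paste(seqid, "genestats", type, start, end, ".", strand, phase, attrs,
          sep = "\t")
  genes <- x$genes
  tx <- x$transcripts
  rows <- x$rows
  tf <- transcript_features(x)
  coding <- stats::setNames(tf$cds_len > 0L, tf$accession)
  for (i in seq_len(nrow(genes))) {
    gid <- genes$gene_id[i]
    gs <- genes$span_start[i]; ge <- genes$span_end[i]
    grows <- rows[rows$gene_id == gid, , drop = FALSE]
    if (is.na(gs) && nrow(grows)) {
      gs <- min(grows$exon_start); ge <- max(grows$exon_end)
    }
    chrom <- if (!is.na(genes$chrom[i])) genes$chrom[i]
             else if (nrow(grows)) grows$chrom[1] else next
    lines <- c(lines, fmt(chrom, "gene", gs, ge, genes$strand[i], ".",
      paste0("ID=", gid, ";Name=", esc(genes$symbol[i]),
             ";gene_biotype=", genes$gene_type[i],
             ";refseq_status=", genes$refseq_status[i],
             ";in_current_annotation=",
             if (isTRUE(genes$in_current_annotation[i])) "true" else "false")))
    for (acc in tx$accession[tx$gene_id == gid]) {
      r <- grows[grows$accession == acc, , drop = FALSE]
      r <- r[order(r$exon_index), , drop = FALSE]
      if (nrow(r) == 0L) next
      ttype <- if (isTRUE(coding[[acc]])) "mRNA" else "transcript"
      lines <- c(lines, fmt(r$chrom[1], ttype, min(r$exon_start),
        max(r$exon_end), r$strand[1], ".",
        paste0("ID=", acc, ";Parent=", gid, ";transcript_id=", acc,
               ";refseq_status=",
               tx$transcript_status[tx$accession == acc])))
      lines <- c(lines, fmt(r$chrom, "exon", r$exon_start, r$exon_end,
                            r$strand, ".", paste0("Parent=", acc)))
      cr <- r[!is.na(r$cds_start), , drop = FALSE]
      if (nrow(cr)) {
        clens <- cr$cds_end - cr$cds_start + 1L
        before <- cumsum(c(0L, clens))[seq_len(nrow(cr))]
        phase <- (3L - before %% 3L) %% 3L
        lines <- c(lines, fmt(cr$chrom, "CDS", cr$cds_start, cr$cds_end,
                              cr$strand, phase, paste0("Parent=", acc)))
      }
    }
  }
  writeLines(lines, path)
  invisible(path)
}

## internal: read one native TSV, enforcing required columns
read_native_file <- function(path, required) {
  d <- utils::read.delim(path, colClasses = "character", sep = "\t",
                         quote = "", na.strings = NULL,
                         stringsAsFactors = FALSE)
  missing <- setdiff(required, names(d))
  if (length(missing))
    stop("file ", basename(path), " lacks required column(s): ",
         paste(missing, collapse = ", "))
  d
}

## internal: "" -> NA, then integer
int_col <- function(v) {
  v[v == ""] <- NA_character_
  as.integer(v)
}

#' Read the native three-table dialect
#'
#' The native dialect mirrors the Gene_Summary / Gene_Table / Gene_Ontology
#' relational layout: `gene_summary.tsv` (one row per gene),
#' `gene_table.tsv` (one row per exon with its downstream intron) and an
#' optional `gene_ontology.tsv`. All files are UTF-8, tab-separated, with
#' a mandatory header; empty strings encode missing values. Numeric
#' columns are parsed as numbers. A `gene_id` in the gene table that is
#' absent from the gene summary is a hard error.
#'
#' @param gene_summary_path,gene_table_path,ontology_path file paths;
#'   `ontology_path` may be `NULL` or point to a non-existent file
#' @return an [annotation_set()]
#' @export
read_native_tables <- function(gene_summary_path, gene_table_path,
                               ontology_path = NULL) {
  gs <- read_native_file(gene_summary_path, NATIVE_GENE_SUMMARY_COLS)
  gt <- read_native_file(gene_table_path, NATIVE_GENE_TABLE_COLS)
  genes <- data.frame(
    gene_id = gs$gene_id, symbol = gs$symbol, gene_type = gs$gene_type,
    chrom = ifelse(gs$chrom == "", NA_character_, gs$chrom),
    strand = gs$strand, refseq_status = gs$refseq_status,
    in_current_annotation = gs$in_current_annotation != "false",
    span_start = int_col(gs$span_start), span_end = int_col(gs$span_end),
    stringsAsFactors = FALSE)
  dangling <- setdiff(gt$gene_id, genes$gene_id)
  if (length(dangling))
    stop("gene_table references unknown gene_id(s): ",
         paste(utils::head(dangling, 5), collapse = ", "))
  chrom_of <- stats::setNames(genes$chrom, genes$gene_id)
  strand_of <- stats::setNames(genes$strand, genes$gene_id)
  rows <- data.frame(
    gene_id = gt$gene_id, accession = gt$accession,
    exon_index = int_col(gt$exon_index),
    chrom = unname(chrom_of[gt$gene_id]),
    strand = unname(strand_of[gt$gene_id]),
    exon_start = int_col(gt$exon_start), exon_end = int_col(gt$exon_end),
    cds_start = int_col(gt$cds_start), cds_end = int_col(gt$cds_end),
    intron_start = int_col(gt$intron_start),
    intron_end = int_col(gt$intron_end),
    exon_seq = NA_character_, coding_seq = NA_character_,
    intron_seq = NA_character_, stringsAsFactors = FALSE)
  tx_first <- !duplicated(gt$accession)
  transcripts <- data.frame(
    accession = gt$accession[tx_first], gene_id = gt$gene_id[tx_first],
    transcript_status = gt$transcript_status[tx_first],
    stringsAsFactors = FALSE)
  ontology <- empty_ontology()
  if (!is.null(ontology_path) && file.exists(ontology_path)) {
    go <- read_native_file(ontology_path, NATIVE_ONTOLOGY_COLS)
    ontology <- go[, NATIVE_ONTOLOGY_COLS, drop = FALSE]
  }
  annotation_set(genes = genes, transcripts = transcripts, rows = rows,
                 ontology = ontology,
                 provenance = paste0("native:", basename(gene_summary_path)))
}

## internal: deterministic TSV writer (no quoting, "" for NA)
write_tsv <- function(d, path) {
  for (col in names(d)) {
    v <- d[[col]]
    if (is.logical(v)) v <- ifelse(v, "true", "false")
    v <- as.character(v)
    v[is.na(v)] <- ""
    d[[col]] <- v
  }
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "", eol = "\n", fileEncoding = "UTF-8")
  invisible(path)
}

#' Write an annotation set as the native dialect plus feature tables
#'
#' Emits `gene_summary.tsv`, `gene_table.tsv`, `gene_ontology.tsv` and the
#' derived `transcript_features.tsv` and `gene_features.tsv`. Column order
#' is fixed and row order deterministic (gene_id, accession, exon_index),
#' so two writes of the same set are byte-identical and
#' `read_native_tables()` recovers the original set.
#'
#' @param x an `annotation_set`
#' @param out_dir output directory (created if needed)
#' @param sequences include sequence columns in `gene_table.tsv`
#'   (off by default: the files get large)
#' @return named character vector of written paths, invisibly
#' @export
write_tables <- function(x, out_dir, sequences = FALSE) {
  stopifnot(inherits(x, "annotation_set"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)
  gs <- x$genes[, NATIVE_GENE_SUMMARY_COLS, drop = FALSE]
  write_tsv(gs, p("gene_summary.tsv"))
  status_of <- stats::setNames(x$transcripts$transcript_status,
                               x$transcripts$accession)
  gt_cols <- NATIVE_GENE_TABLE_COLS
  if (sequences) gt_cols <- c(gt_cols, "exon_seq", "coding_seq", "intron_seq")
  gt <- x$rows
  gt$transcript_status <- unname(status_of[gt$accession])
  write_tsv(gt[, gt_cols, drop = FALSE], p("gene_table.tsv"))
  write_tsv(x$ontology[, NATIVE_ONTOLOGY_COLS, drop = FALSE],
            p("gene_ontology.tsv"))
  tf <- transcript_features(x)
  write_tsv(tf, p("transcript_features.tsv"))
  write_tsv(gene_features(x, tf), p("gene_features.tsv"))
  invisible(c(gene_summary = p("gene_summary.tsv"),
              gene_table = p("gene_table.tsv"),
              gene_ontology = p("gene_ontology.tsv"),
              transcript_features = p("transcript_features.tsv"),
              gene_features = p("gene_features.tsv")))
}
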