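## The dynamic-statistics engine: filter specifications, summary statistics
## with record identity, feature summaries with redundancy/positional
## options, per-chromosome breakdowns, the splice census, genome-fraction
## reports and QC flags.

#' Filter clause constructors
#'
#' Clauses are combined with AND by [filter_spec()]. `flt_equals`,
#' `flt_in`, `flt_range` (numeric, inclusive), `flt_prefix`/`flt_suffix`/
#' `flt_contains` (fixed strings) address a column of the filtered table;
#' `flt_gene_has_transcript_status` selects genes owning at least one
#' transcript whose status is in `statuses` (it requires the annotation
#' set for context and only applies to the genes table).
#'
#' @param field column name in the filtered table
#' @param value,values,statuses clause payload
#' @param lo,hi inclusive numeric bounds (may be `-Inf`/`Inf`)
#' @return a filter clause object
#' @name filter_clauses
NULL

#' @rdname filter_clauses
#' @export
flt_equals <- function(field, value)
  structure(list(op = "equals", field = field, value = value),
            class = "filter_clause")
#' @rdname filter_clauses
#' @export
flt_in <- function(field, values)
  structure(list(op = "in", field = field, values = values),
            class = "filter_clause")
#' @rdname filter_clauses
#' @export
flt_range <- function(field, lo = -Inf, hi = Inf)
  structure(list(op = "range", field = field, lo = lo, hi = hi),
            class = "filter_clause")
#' @rdname filter_clauses
#' @export
flt_prefix <- function(field, value)
  structure(list(op = "prefix", field = field, value = value),
            class = "filter_clause")
#' @rdname filter_clauses
#' @export
flt_suffix <- function(field, value)
  structure(list(op = "suffix", field = field, value = value),
            class = "filter_clause")
#' @rdname filter_clauses
#' @export
flt_contains <- function(field, value)
  structure(list(op = "contains", field = field, value = value),
            class = "filter_clause")
#' @rdname filter_clauses
#' @export
flt_gene_has_transcript_status <- function(statuses)
  structure(list(op = "gene_has_transcript_status", statuses = statuses),
            class = "filter_clause")

#' Build a filter specification
#'
#' A conjunction (AND) of clauses; an empty specification selects all
#' records.
#'
#' @param ... filter clauses (see [filter_clauses])
#' @return an object of class `filter_spec`
#' @export
filter_spec <- function(...) {
  clauses <- list(...)
  if (length(clauses) == 1L && is.list(clauses[[1]]) &&
      !inherits(clauses[[1]], "filter_clause"))
    clauses <- clauses[[1]]
  ok <- vapply(clauses, inherits, logical(1), "filter_clause")
  if (!all(ok)) stop("all arguments must be filter clauses")
  structure(list(clauses = clauses), class = "filter_spec")
}

#' Parse a filter specification from JSON
#'
#' The JSON form is an array of objects with an `op` field
#' (`equals`, `in`, `range`, `prefix`, `suffix`, `contains`,
#' `gene_has_transcript_status`) and the clause payload
#' (`field` + `value`/`values`/`lo`,`hi`/`statuses`).
#'
#' @param json a JSON string or path to a JSON file
#' @return a [filter_spec()]
#' @export
parse_filter_spec <- function(json) {
  x <- jsonlite::fromJSON(json, simplifyDataFrame = FALSE)
  clauses <- lapply(x, function(cl) {
    switch(cl$op,
      equals = flt_equals(cl$field, cl$value),
      `in` = flt_in(cl$field, unlist(cl$values)),
      range = flt_range(cl$field,
                        if (is.null(cl$lo)) -Inf else cl$lo,
                        if (is.null(cl$hi)) Inf else cl$hi),
      prefix = flt_prefix(cl$field, cl$value),
      suffix = flt_suffix(cl$field, cl$value),
      contains = flt_contains(cl$field, cl$value),
      gene_has_transcript_status =
        flt_gene_has_transcript_status(unlist(cl$statuses)),
      stop("unknown filter op: ", cl$op))
  })
  filter_spec(clauses)
}

## internal: evaluate one clause to a logical vector over df
eval_clause <- function(cl, df, aset = NULL) {
  if (cl$op == "gene_has_transcript_status") {
    if (is.null(aset) || !"gene_id" %in% names(df))
      stop("gene_has_transcript_status requires the annotation set and a ",
           "gene table")
    good <- unique(aset$transcripts$gene_id[
      aset$transcripts$transcript_status %in% cl$statuses])
    return(df$gene_id %in% good)
  }
  if (!cl$field %in% names(df))
    stop("unknown field in filter: ", cl$field)
  v <- df[[cl$field]]
  res <- switch(cl$op,
    equals = v == cl$value,
    `in` = v %in% cl$values,
    range = { vn <- as.numeric(v); vn >= cl$lo & vn <= cl$hi },
    prefix = startsWith(as.character(v), cl$value),
    suffix = endsWith(as.character(v), cl$value),
    contains = grepl(cl$value, as.character(v), fixed = TRUE),
    stop("unknown filter op: ", cl$op))
  res & !is.na(res)
}

#' Apply a filter specification to a table
#'
#' Rows satisfying every clause are kept, in their original order. Records
#' with a missing value in a filtered field never satisfy the clause.
#'
#' @param df the table (e.g. `x$rows`, [row_features()], genes, or a
#'   feature table)
#' @param spec a [filter_spec()]
#' @param aset the annotation set, needed only for gene-level clauses that
#'   look across tables
#' @return the filtered data.frame
#' @export
apply_filter <- function(df, spec, aset = NULL) {
  stopifnot(inherits(spec, "filter_spec"))
  keep <- rep(TRUE, nrow(df))
  for (cl in spec$clauses) keep <- keep & eval_clause(cl, df, aset)
  out <- df[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Rows table with derived length columns
#'
#' Adds `exon_len`, `coding_len`, `intron_len`, the accession prefix and
#' the positional class of each exon, so that filters and summaries can
#' address them by name.
#'
#' @param x an `annotation_set` or its `rows` table
#' @return the rows table with derived columns appended
#' @export
row_features <- function(x) {
  rows <- if (inherits(x, "annotation_set")) x$rows else x
  rows$exon_len <- rows$exon_end - rows$exon_start + 1L
  rows$coding_len <- rows$cds_end - rows$cds_start + 1L
  rows$intron_len <- rows$intron_end - rows$intron_start + 1L
  rows$accession_prefix <- accession_prefix(rows$accession)
  if (nrow(rows)) {
    nex <- stats::ave(rows$exon_index, rows$accession, FUN = max)
    rows$position_class <- exon_position_class(nex, rows$exon_index)
  } else {
    rows$position_class <- character(0)
  }
  rows
}

#' Curated subset of an annotation set
#'
#' Reproduces the curated-selection rule used for reference statistics: a
#' gene is kept iff its own RefSeq status is REVIEWED or VALIDATED, it is
#' in the current annotation release, and it owns at least one REVIEWED or
#' VALIDATED transcript. Transcript-level (and sequence-level) work is
#' additionally restricted to curated accession prefixes: only `NM_` and
#' `NR_` transcripts of the kept genes are retained, excluding `XM_`/`XR_`
#' model records produced by automated pipelines.
#'
#' @param x an `annotation_set`
#' @return an `annotation_set` containing the curated genes, transcripts
#'   and rows (ontology restricted to curated genes)
#' @export
curated_subset <- function(x) {
  stopifnot(inherits(x, "annotation_set"))
  tx <- x$transcripts
  good_status <- c("REVIEWED", "VALIDATED")
  genes_with_cur_tx <- unique(tx$gene_id[tx$transcript_status %in% good_status])
  gkeep <- x$genes$refseq_status %in% good_status &
    x$genes$in_current_annotation %in% TRUE &
    x$genes$gene_id %in% genes_with_cur_tx
  genes <- x$genes[gkeep, , drop = FALSE]
  tkeep <- tx$gene_id %in% genes$gene_id &
    accession_prefix(tx$accession) %in% c("NM_", "NR_")
  transcripts <- tx[tkeep, , drop = FALSE]
  rows <- x$rows[x$rows$accession %in% transcripts$accession, , drop = FALSE]
  ontology <- x$ontology[x$ontology$gene_id %in% genes$gene_id, , drop = FALSE]
  annotation_set(genes = genes, transcripts = transcripts, rows = rows,
                 ontology = ontology,
                 provenance = paste0(x$provenance, " [curated]"))
}

#' Summary statistics with record identity
#'
#' Computes n, median (midpoint convention for even n), mean, sample
#' standard deviation (n-1 denominator, missing for n = 1), total, and the
#' minimum and maximum each paired with *all* identifiers attaining them —
#' so the extreme values can always be traced back to the records having
#' them. Missing values are dropped together with their identifiers.
#'
#' @param values numeric vector
#' @param ids parallel identifiers (defaults to positions)
#' @return an object of class `summary_stats`: list with fields `n`,
#'   `median`, `mean`, `sd`, `total`, `min_value`, `min_ids`, `max_value`,
#'   `max_ids`
#' @examples
#' summary_stats(c(1, 2, 3), c("a", "b", "c"))
#' @export
summary_stats <- function(values, ids = NULL) {
  if (!is.numeric(values)) stop("values must be numeric")
  if (is.null(ids)) ids <- as.character(seq_along(values))
  if (length(ids) != length(values)) stop("ids must parallel values")
  keep <- !is.na(values)
  values <- values[keep]; ids <- ids[keep]
  n <- length(values)
  if (n == 0L) {
    out <- list(n = 0L, median = NA_real_, mean = NA_real_, sd = NA_real_,
                total = NA_real_, min_value = NA_real_,
                min_ids = character(), max_value = NA_real_,
                max_ids = character())
  } else {
    mn <- min(values); mx <- max(values)
    out <- list(n = n,
                median = as.numeric(stats::median(values)),
                mean = mean(values),
                sd = if (n > 1L) stats::sd(values) else NA_real_,
                total = sum(values),
                min_value = as.numeric(mn),
                min_ids = sort(unique(ids[values == mn])),
                max_value = as.numeric(mx),
                max_ids = sort(unique(ids[values == mx])))
  }
  class(out) <- "summary_stats"
  out
}

#' @export
print.summary_stats <- function(x, ...) {
  cat(sprintf("n=%d  median=%s  mean=%s  sd=%s  total=%s\n", x$n,
              format(x$median), format(x$mean), format(x$sd),
              format(x$total)))
  if (x$n > 0L) {
    cat(sprintf("min=%s (%s)\nmax=%s (%s)\n",
                format(x$min_value),
                paste(utils::head(x$min_ids, 5), collapse = ","),
                format(x$max_value),
                paste(utils::head(x$max_ids, 5), collapse = ",")))
  }
  invisible(x)
}

PER_ROW_FEATURES <- c("exon_len", "coding_len", "intron_len")
PER_TX_FEATURES <- c("mature_len", "cds_len", "utr5_len", "utr3_len",
                     "n_exons", "n_coding_exons", "n_introns")
PER_GENE_FEATURES <- c("gene_len", "n_transcripts", "max_exons",
                       "max_coding_exons")

#' Summary of a feature over an annotation subset
#'
#' Assembles the values of one feature at the requested level and passes
#' them to [summary_stats()]. Per-row features (`exon_len`, `coding_len`,
#' `intron_len`) support `redundancy = "non_redundant"`, which collapses
#' shared coordinates via [nonredundant_set()] before summarizing (member
#' identifiers become `chrom:start-end(strand)` keys), and the positional
#' options `exclude_last_exons` (drops transcription-last exons; exons of
#' single-exon transcripts are also dropped, their only exon being
#' terminal) and `last_exons_only`. Positional filtering is applied before
#' redundancy collapsing. Per-transcript and per-gene features come from
#' [transcript_features()] and [gene_features()].
#'
#' @param x an `annotation_set` (pre-filter it, e.g. with
#'   [curated_subset()], to change the population)
#' @param feature feature name (see details)
#' @param level `"per_row"`, `"per_transcript"` or `"per_gene"`
#' @param redundancy `"redundant"` (default) or `"non_redundant"`
#' @param exclude_last_exons,last_exons_only positional options for exon
#'   features
#' @param filter optional [filter_spec()] applied to the level's table
#'   (for per-row levels the table is [row_features()])
#' @return a [summary_stats()] object with the options recorded in
#'   attributes
#' @export
feature_summary <- function(x, feature,
                            level = c("per_row", "per_transcript",
                                      "per_gene"),
                            redundancy = c("redundant", "non_redundant"),
                            exclude_last_exons = FALSE,
                            last_exons_only = FALSE,
                            filter = NULL) {
  stopifnot(inherits(x, "annotation_set"))
  level <- match.arg(level)
  redundancy <- match.arg(redundancy)
  if (exclude_last_exons && last_exons_only)
    stop("exclude_last_exons and last_exons_only are mutually exclusive")
  if (redundancy == "non_redundant" && level != "per_row")
    stop("non_redundant applies only to per_row features (not ", feature, ")")
  if ((exclude_last_exons || last_exons_only) &&
      !(level == "per_row" && feature %in% c("exon_len", "coding_len")))
    stop("last-exon options apply only to per_row exon features")

  if (level == "per_row") {
    if (!feature %in% PER_ROW_FEATURES)
      stop("unknown per_row feature: ", feature)
    rows <- row_features(x)
    if (!is.null(filter)) rows <- apply_filter(rows, filter, x)
    if (exclude_last_exons)
      rows <- rows[!rows$position_class %in% c("last", "single"), ,
                   drop = FALSE]
    if (last_exons_only)
      rows <- rows[rows$position_class == "last", , drop = FALSE]
    if (redundancy == "non_redundant") {
      kind <- switch(feature, exon_len = "exon", coding_len = "coding_exon",
                     intron_len = "intron")
      nr <- nonredundant_set(rows, kind)
      values <- if (nrow(nr)) nr$end - nr$start + 1L else integer()
      ids <- if (nrow(nr))
        paste0(nr$chrom, ":", nr$start, "-", nr$end, "(", nr$strand, ")")
      else character()
    } else {
      values <- rows[[feature]]
      ids <- if (nrow(rows))
        paste0(rows$accession, ":", rows$exon_index) else character()
    }
    res <- summary_stats(values, ids)
  } else if (level == "per_transcript") {
    if (!feature %in% PER_TX_FEATURES)
      stop("unknown per_transcript feature: ", feature)
    tf <- transcript_features(x)
    if (!is.null(filter)) tf <- apply_filter(tf, filter, x)
    res <- summary_stats(as.numeric(tf[[feature]]), tf$accession)
  } else {
    if (!feature %in% PER_GENE_FEATURES)
      stop("unknown per_gene feature: ", feature)
    gf <- gene_features(x)
    if (!is.null(filter)) gf <- apply_filter(gf, filter, x)
    res <- summary_stats(as.numeric(gf[[feature]]), gf$gene_id)
  }
  attr(res, "feature") <- feature
  attr(res, "level") <- level
  attr(res, "options") <- list(redundancy = redundancy,
                               exclude_last_exons = exclude_last_exons,
                               last_exons_only = last_exons_only)
  res
}

GENE_TYPE_GROUPS <- c("protein-coding" = "protein_coding",
                      "pseudo" = "pseudo",
                      "ncRNA" = "noncoding", "snoRNA" = "noncoding",
                      "snRNA" = "noncoding", "rRNA" = "noncoding",
                      "tRNA" = "tRNA", "other" = "other",
                      "unknown" = "unknown")

#' Per-chromosome, per-type-group gene counts
#'
#' Gene types are grouped as protein-coding, pseudogenes, non-coding
#' (ncRNA + snoRNA + snRNA + rRNA), with tRNA, other and unknown tallied
#' separately. Genes with a missing or unknown chromosome are tallied
#' under `"unplaced"` and excluded from any per-chromosome averaging.
#'
#' @param genes a genes table (e.g. `x$genes`, possibly filtered)
#' @return data.frame of counts with columns `chrom`, `group`, `n`; the
#'   grand total (equal to `nrow(genes)`) is attached as attribute `total`
#' @export
chromosome_breakdown <- function(genes) {
  chrom <- genes$chrom
  chrom[is.na(chrom) | chrom == "" | chrom == "unknown"] <- "unplaced"
  group <- unname(GENE_TYPE_GROUPS[genes$gene_type])
  tab <- table(chrom = chrom, group = group)
  out <- as.data.frame(tab, stringsAsFactors = FALSE)
  names(out) <- c("chrom", "group", "n")
  out <- out[out$n > 0L, , drop = FALSE]
  out <- out[order(out$chrom, out$group), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "total") <- nrow(genes)
  out
}

#' Splice-site census over a row subset
#'
#' Classifies every intron of length >= 4 bp with an available sequence
#' (from the attached `intron_seq` column, or extracted from `asm`) into
#' the six splice categories and reports counts and percentages of the
#' classified total. Percentages are kept at full precision; display
#' rounding is half-up to 2 decimals.
#'
#' @param rows a rows table (e.g. from a curated set)
#' @param asm optional [genome_assembly()] used when sequences are not
#'   attached
#' @return data.frame with columns `category`, `n`, `pct`; the number of
#'   introns excluded as too short is attached as attribute
#'   `n_too_short`
#' @export
splice_census <- function(rows, asm = NULL) {
  has_intron <- !is.na(rows$intron_start)
  r <- rows[has_intron, , drop = FALSE]
  ilen <- r$intron_end - r$intron_start + 1L
  long_enough <- ilen >= 4L
  r <- r[long_enough, , drop = FALSE]
  seqs <- r$intron_seq
  need <- is.na(seqs)
  if (any(need)) {
    if (is.null(asm))
      stop("intron sequences not attached and no assembly provided")
    seqs[need] <- extract_sequence(asm, data.frame(
      chrom = r$chrom[need], start = r$intron_start[need],
      end = r$intron_end[need], strand = r$strand[need]))
  }
  dn <- splice_dinucleotides(seqs)
  cats <- classify_splice(dn$donor, dn$acceptor)
  counts <- table(factor(cats, levels = SPLICE_CATEGORIES))
  total <- sum(counts)
  out <- data.frame(category = SPLICE_CATEGORIES,
                    n = as.integer(counts),
                    pct = if (total > 0) 100 * as.integer(counts) / total
                          else rep(NA_real_, length(SPLICE_CATEGORIES)),
                    stringsAsFactors = FALSE)
  attr(out, "n_too_short") <- sum(!long_enough)
  out
}

#' Round half-up at a given number of decimals
#'
#' Display convention for percentages (base R's `round()` rounds half to
#' even).
#'
#' @param x numeric
#' @param digits decimal places
#' @return rounded numeric
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Genome-fraction report
#'
#' Relates the curated gene set to the assembly: the fractions of the
#' genome covered by protein-coding genes, by non-protein-coding genes and
#' by both combined; the fraction of protein-coding gene DNA that is part
#' of a mature mRNA (non-redundant exon total over gene-length total); the
#' non-redundant exon and coding-exon totals as fractions of the genome;
#' the coding fraction of exon sequence; and the fractions of intronless
#' (monoexonic) transcripts and of multi-isoform genes. Exon-level
#' numerators use the non-redundant sets over the rows of NM_ transcripts
#' of protein-coding genes.
#'
#' @param x a curated `annotation_set` (see [curated_subset()])
#' @param asm a [genome_assembly()]; only `lengths` are needed
#' @return data.frame with columns `metric`, `numerator`, `denominator`,
#'   `pct`; a zero denominator yields `NA` with a warning
#' @export
genome_fraction_report <- function(x, asm) {
  stopifnot(inherits(x, "annotation_set"), inherits(asm, "genome_assembly"))
  genome_total <- sum(as.numeric(asm$lengths))
  tf <- transcript_features(x)
  gf <- gene_features(x, tf)
  is_pc <- x$genes$gene_type == "protein-coding"
  pc_gene_total <- sum(as.numeric(gf$gene_len[match(
    x$genes$gene_id[is_pc], gf$gene_id)]), na.rm = TRUE)
  nc_gene_total <- sum(as.numeric(gf$gene_len[match(
    x$genes$gene_id[!is_pc], gf$gene_id)]), na.rm = TRUE)

  pc_nm <- x$transcripts$accession[
    x$transcripts$gene_id %in% x$genes$gene_id[is_pc] &
      accession_prefix(x$transcripts$accession) == "NM_"]
  pc_rows <- x$rows[x$rows$accession %in% pc_nm, , drop = FALSE]
  nr_exon <- nonredundant_set(pc_rows, "exon")
  nr_cds <- nonredundant_set(pc_rows, "coding_exon")
  nr_exon_total <- sum(as.numeric(nr_exon$end - nr_exon$start + 1L))
  nr_cds_total <- sum(as.numeric(nr_cds$end - nr_cds$start + 1L))

  n_tx <- nrow(x$transcripts)
  n_mono <- sum(tf$is_monoexonic)
  n_genes <- nrow(x$genes)
  n_multi <- sum(gf$n_transcripts >= 2L)

  frac <- function(metric, num, den) {
    if (is.na(den) || den == 0) {
      warning("zero denominator for ", metric)
      pct <- NA_real_
    } else pct <- 100 * num / den
    data.frame(metric = metric, numerator = num, denominator = den,
               pct = pct, stringsAsFactors = FALSE)
  }
  out <- rbind(
    frac("pc_gene_fraction", pc_gene_total, genome_total),
    frac("nc_gene_fraction", nc_gene_total, genome_total),
    frac("combined_gene_fraction", pc_gene_total + nc_gene_total,
         genome_total),
    frac("mrna_fraction_of_gene_dna", nr_exon_total, pc_gene_total),
    frac("exon_fraction_of_genome", nr_exon_total, genome_total),
    frac("coding_fraction_of_exons", nr_cds_total, nr_exon_total),
    frac("coding_fraction_of_genome", nr_cds_total, genome_total),
    frac("intronless_transcript_fraction", n_mono, n_tx),
    frac("multi_isoform_gene_fraction", n_multi, n_genes))
  rownames(out) <- NULL
  out
}

#' Quality-control flags
#'
#' Flags (never drops) records that look artefactual or incomplete:
#' introns shorter than 30 bp (no validated intron of any species is
#' shorter), exons shorter than 2 bp, coding transcripts with a 0 bp 5' or
#' 3' UTR (often only the CDS was registered), CDS lengths that are not a
#' multiple of 3 (annotated CDSs may be incomplete), and coding
#' transcripts whose CDS is non-contiguous in transcript space. Whether to
#' exclude flagged records from a statistic is the caller's filter choice.
#'
#' @param x an `annotation_set`
#' @return data.frame with columns `record_id`, `rule`, `value`
#' @export
qc_flags <- function(x) {
  stopifnot(inherits(x, "annotation_set"))
  rows <- row_features(x)
  tf <- transcript_features(x)
  out <- list()
  bad_i <- which(!is.na(rows$intron_len) & rows$intron_len < 30L)
  if (length(bad_i))
    out <- c(out, list(data.frame(
      record_id = paste0(rows$accession[bad_i], ":", rows$exon_index[bad_i]),
      rule = "intron_lt_30", value = rows$intron_len[bad_i],
      stringsAsFactors = FALSE)))
  bad_e <- which(rows$exon_len < 2L)
  if (length(bad_e))
    out <- c(out, list(data.frame(
      record_id = paste0(rows$accession[bad_e], ":", rows$exon_index[bad_e]),
      rule = "exon_lt_2", value = rows$exon_len[bad_e],
      stringsAsFactors = FALSE)))
  coding <- tf[tf$cds_len > 0L, , drop = FALSE]
  u5 <- which(coding$utr5_len == 0L)
  if (length(u5))
    out <- c(out, list(data.frame(record_id = coding$accession[u5],
                                  rule = "utr5_zero", value = 0L,
                                  stringsAsFactors = FALSE)))
  u3 <- which(coding$utr3_len == 0L)
  if (length(u3))
    out <- c(out, list(data.frame(record_id = coding$accession[u3],
                                  rule = "utr3_zero", value = 0L,
                                  stringsAsFactors = FALSE)))
  m3 <- which(coding$cds_len %% 3L != 0L)
  if (length(m3))
    out <- c(out, list(data.frame(record_id = coding$accession[m3],
                                  rule = "cds_not_triplet",
                                  value = coding$cds_len[m3],
                                  stringsAsFactors = FALSE)))
  gap <- which(coding$utr5_len + coding$cds_len + coding$utr3_len !=
                 coding$mature_len)
  if (length(gap))
    out <- c(out, list(data.frame(record_id = coding$accession[gap],
                                  rule = "cds_noncontiguous",
                                  value = coding$cds_len[gap],
                                  stringsAsFactors = FALSE)))
  if (length(out) == 0L)
    return(data.frame(record_id = character(), rule = character(),
                      value = integer(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res <- res[order(res$rule, res$record_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}
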