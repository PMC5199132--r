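#' Infer introns from a transcript's exons
#'
#' An intron is the genomic gap between two transcription-consecutive exons.
#' Introns are returned in transcription order, so on the minus strand
#' intron 1 lies at the highest genomic coordinates. Abutting exons (zero
#' gap) are an annotation defect and raise an error rather than being
#' silently merged, since they would corrupt intron statistics.
#'
#' @param exons interval data.frame in transcription order
#' @param accession optional transcript name used in error messages
#' @return interval data.frame of introns (`n_exons - 1` rows)
#' @examples
#' infer_introns(genomic_interval("c", c(100, 300, 500), c(200, 400, 600)))
#' @export
infer_introns <- function(exons, accession = NULL) {
  n <- nrow(exons)
  if (n <= 1L) return(empty_intervals())
  g <- exons[order(exons$start), , drop = FALSE]
  istart <- g$end[-n] + 1L
  iend <- g$start[-1] - 1L
  if (any(istart > iend))
    stop("abutting or overlapping exons",
         if (!is.null(accession)) paste0(" in transcript ", accession),
         " (no intron gap at ",
         paste0(g$end[-n][istart > iend], "/", g$start[-1][istart > iend],
                collapse = ", "), ")")
  out <- data.frame(chrom = g$chrom[-n], start = istart, end = iend,
                    strand = g$strand[-n], stringsAsFactors = FALSE)
  if (exons$strand[1] == "-") out <- out[rev(seq_len(n - 1L)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Coding part of each exon
#'
#' Intersects each exon with the union of the CDS segments, yielding the
#' protein-coding portion of the exon (stop codon included, since CDS
#' segments are taken as annotated, i.e. stop-inclusive). Exons with no
#' coding portion yield `NA`. A coding part of a single base is legal.
#'
#' @param exons interval data.frame in transcription order
#' @param cds_segments interval data.frame (genomic spans or per-exon
#'   pieces) or `NULL` for non-coding transcripts
#' @param accession optional transcript name for error messages
#' @return data.frame with `start`/`end` columns parallel to `exons`
#'   (`NA` where the exon is entirely non-coding)
#' @export
coding_exon_intervals <- function(exons, cds_segments = NULL, accession = NULL) {
  n <- nrow(exons)
  out <- data.frame(start = rep(NA_integer_, n), end = rep(NA_integer_, n))
  if (is.null(cds_segments) || nrow(cds_segments) == 0L) return(out)
  who <- if (is.null(accession)) "" else paste0(" in transcript ", accession)
  seg_hit <- rep(FALSE, nrow(cds_segments))
  for (i in seq_len(n)) {
    s <- pmax(exons$start[i], cds_segments$start)
    e <- pmin(exons$end[i], cds_segments$end)
    hit <- which(s <= e)
    seg_hit[hit] <- TRUE
    if (length(hit) == 0L) next
    # merge touching/overlapping pieces within this exon; a disconnected
    # coding region inside one exon is not representable in a row record
    o <- hit[order(s[hit])]
    if (length(o) > 1L && any(s[o][-1] > e[o][-length(o)] + 1L))
      stop("disconnected CDS within one exon", who)
    out$start[i] <- min(s[hit])
    out$end[i] <- max(e[hit])
  }
  # a CDS segment touching no exon at all is a hard error; segments that
  # extend across introns are clipped by the intersection above
  if (any(!seg_hit))
    stop("CDS segment(s) entirely outside exons", who, ": ",
         paste0("[", cds_segments$start[!seg_hit], ",",
                cds_segments$end[!seg_hit], "]", collapse = " "))
  out
}

## internal: features of one transcript from its exons (transcription order)
## and per-exon coding parts. UTRs are measured in transcript coordinates:
## 5' UTR = exonic bases strictly upstream of the first coding base.
transcript_features_one <- function(exons, parts) {
  lens <- interval_length(exons)
  mature <- sum(lens)
  n <- nrow(exons)
  coding <- which(!is.na(parts$start))
  if (length(coding) == 0L)
    return(list(mature_len = mature, cds_len = 0L, utr5_len = 0L,
                utr3_len = 0L, n_exons = n, n_coding_exons = 0L))
  offset <- cumsum(c(0L, lens))[seq_len(n)]
  t1 <- integer(0); t2 <- integer(0); cds_len <- 0L
  minus <- exons$strand[1] == "-"
  for (i in coding) {
    cs <- parts$start[i]; ce <- parts$end[i]
    if (minus) {
      t1 <- c(t1, offset[i] + exons$end[i] - ce + 1L)
      t2 <- c(t2, offset[i] + exons$end[i] - cs + 1L)
    } else {
      t1 <- c(t1, offset[i] + cs - exons$start[i] + 1L)
      t2 <- c(t2, offset[i] + ce - exons$start[i] + 1L)
    }
    cds_len <- cds_len + (ce - cs + 1L)
  }
  list(mature_len = mature, cds_len = cds_len,
       utr5_len = min(t1) - 1L, utr3_len = mature - max(t2),
       n_exons = n, n_coding_exons = length(coding))
}

#' Per-transcript derived features
#'
#' Computes, for every transcript of an annotation set, the mature (spliced)
#' transcript length, CDS length (0 for non-coding transcripts, stop codon
#' included otherwise), 5' and 3' UTR lengths measured in transcription
#' direction, and exon/coding-exon/intron counts. For coding transcripts
#' with a contiguous CDS, `mature_len = utr5_len + cds_len + utr3_len`.
#' Isoform-specific intron structure is handled naturally because every
#' transcript carries its own exon chain.
#'
#' @param x an `annotation_set`
#' @return data.frame with one row per transcript: accession, gene_id,
#'   mature_len, cds_len, utr5_len, utr3_len, n_exons, n_coding_exons,
#'   n_introns, is_monoexonic
#' @export
transcript_features <- function(x) {
  stopifnot(inherits(x, "annotation_set"))
  rows <- x$rows
  if (nrow(rows) == 0L) {
    return(data.frame(accession = character(), gene_id = character(),
                      mature_len = integer(), cds_len = integer(),
                      utr5_len = integer(), utr3_len = integer(),
                      n_exons = integer(), n_coding_exons = integer(),
                      n_introns = integer(), is_monoexonic = logical(),
                      stringsAsFactors = FALSE))
  }
  pieces <- lapply(split(rows, rows$accession), function(r) {
    r <- r[order(r$exon_index), , drop = FALSE]
    exons <- data.frame(chrom = r$chrom, start = r$exon_start,
                        end = r$exon_end, strand = r$strand,
                        stringsAsFactors = FALSE)
    f <- transcript_features_one(exons, data.frame(start = r$cds_start,
                                                   end = r$cds_end))
    data.frame(accession = r$accession[1], gene_id = r$gene_id[1],
               mature_len = f$mature_len, cds_len = f$cds_len,
               utr5_len = f$utr5_len, utr3_len = f$utr3_len,
               n_exons = f$n_exons, n_coding_exons = f$n_coding_exons,
               n_introns = f$n_exons - 1L,
               is_monoexonic = f$n_exons == 1L, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  out <- out[order(out$gene_id, out$accession), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-gene derived features
#'
#' Gene length is the genomic envelope of the union of all exons of all the
#' gene's transcripts (max end - min start + 1). Genes without transcripts
#' fall back to their annotated span, which makes a length available for
#' e.g. tRNA genes annotated with a genomic location only; genes with
#' neither get `NA` (missing, not zero). `max_exons`/`max_coding_exons`
#' describe the isoform with the most exons, ties broken by the
#' lexicographically smallest accession.
#'
#' @param x an `annotation_set` (possibly already subset, e.g. curated)
#' @param tf optional precomputed [transcript_features()] table
#' @return data.frame with one row per gene: gene_id, gene_len,
#'   n_transcripts, max_exons, max_coding_exons
#' @export
gene_features <- function(x, tf = NULL) {
  stopifnot(inherits(x, "annotation_set"))
  if (is.null(tf)) tf <- transcript_features(x)
  genes <- x$genes
  rows <- x$rows
  env <- if (nrow(rows)) {
    lo <- tapply(rows$exon_start, rows$gene_id, min)
    hi <- tapply(rows$exon_end, rows$gene_id, max)
    data.frame(gene_id = names(lo), lo = as.integer(lo), hi = as.integer(hi),
               stringsAsFactors = FALSE)
  } else data.frame(gene_id = character(), lo = integer(), hi = integer())
  gl <- rep(NA_integer_, nrow(genes))
  m <- match(genes$gene_id, env$gene_id)
  has <- !is.na(m)
  gl[has] <- env$hi[m[has]] - env$lo[m[has]] + 1L
  fb <- !has & !is.na(genes$span_start)
  gl[fb] <- genes$span_end[fb] - genes$span_start[fb] + 1L

  ntx <- table(x$transcripts$gene_id)
  n_transcripts <- as.integer(ntx[genes$gene_id])
  n_transcripts[is.na(n_transcripts)] <- 0L

  max_exons <- rep(NA_integer_, nrow(genes))
  max_coding <- rep(NA_integer_, nrow(genes))
  if (nrow(tf)) {
    tf_o <- tf[order(tf$gene_id, -tf$n_exons, tf$accession), , drop = FALSE]
    top <- tf_o[!duplicated(tf_o$gene_id), , drop = FALSE]
    mm <- match(genes$gene_id, top$gene_id)
    max_exons <- top$n_exons[mm]
    max_coding <- top$n_coding_exons[mm]
  }
  out <- data.frame(gene_id = genes$gene_id, gene_len = gl,
                    n_transcripts = n_transcripts,
                    max_exons = max_exons, max_coding_exons = max_coding,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Positional class of an exon within its transcript
#'
#' Classes follow transcription order, so on the minus strand the last exon
#' is the one with the smallest genomic coordinates. Used e.g. to exclude
#' last exons, which are usually the longest, from exon-length statistics.
#'
#' @param n_exons exon count(s) of the transcript
#' @param exon_index 1-based ordinal(s) in transcription order
#' @return character vector: `"single"`, `"first"`, `"internal"` or `"last"`
#' @export
exon_position_class <- function(n_exons, exon_index) {
  if (any(exon_index < 1L | exon_index > n_exons))
    stop("exon_index out of range")
  ifelse(n_exons == 1L, "single",
         ifelse(exon_index == 1L, "first",
                ifelse(exon_index == n_exons, "last", "internal")))
}
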