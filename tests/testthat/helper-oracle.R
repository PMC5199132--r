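# Test-local oracles and toy builders. These deliberately re-derive
# expectations with brute-force or constructive logic that is independent
# of the package's implementation paths.

iv <- function(start, end, chrom = "chrT", strand = "+") {
  data.frame(chrom = chrom, start = as.integer(start), end = as.integer(end),
             strand = strand, stringsAsFactors = FALSE)
}

# Enumerate a transcript's exonic genomic positions in transcription order.
tx_positions <- function(exons) {
  unlist(lapply(seq_len(nrow(exons)), function(i) {
    p <- exons$start[i]:exons$end[i]
    if (exons$strand[i] == "-") rev(p) else p
  }))
}

# Brute-force per-base labeler: label every exonic base as 5' UTR, coding
# or 3' UTR by position relative to the first/last coding base.
oracle_utr_cds <- function(exons, parts) {
  pos <- tx_positions(exons)
  coding <- rep(FALSE, length(pos))
  for (i in which(!is.na(parts$start)))
    coding <- coding | (pos >= parts$start[i] & pos <= parts$end[i])
  if (!any(coding))
    return(list(mature = length(pos), utr5 = 0L, cds = 0L, utr3 = 0L))
  w <- which(coding)
  list(mature = length(pos), utr5 = w[1] - 1L, cds = sum(coding),
       utr3 = length(pos) - w[length(w)])
}

# Random transcript with a CDS chosen as a transcript-coordinate window
# [i, j]; the expected UTR/CDS lengths follow directly from i and j, so
# they are known without running any package code. Genomic CDS parts are
# derived by grouping the selected positions per exon.
random_transcript_case <- function(max_exons = 30L) {
  n_ex <- sample.int(max_exons, 1L)
  strand <- sample(c("+", "-"), 1L)
  lens <- sample(1:200, n_ex, replace = TRUE)
  gaps <- if (n_ex > 1L) sample(30:500, n_ex - 1L, replace = TRUE) else
    integer()
  starts <- cumsum(c(1L, lens[-n_ex] + gaps))
  ex <- iv(starts, starts + lens - 1L, strand = strand)
  if (strand == "-") ex <- ex[rev(seq_len(n_ex)), , drop = FALSE]
  rownames(ex) <- NULL
  n <- sum(lens)
  coding <- runif(1) < 0.8
  parts <- data.frame(start = rep(NA_integer_, n_ex),
                      end = rep(NA_integer_, n_ex))
  if (coding) {
    i <- sample.int(n, 1L)
    j <- i + sample.int(n - i + 1L, 1L) - 1L
    pos <- tx_positions(ex)
    sel <- pos[i:j]
    for (k in seq_len(n_ex)) {
      here <- sel[sel >= ex$start[k] & sel <= ex$end[k]]
      if (length(here)) {
        parts$start[k] <- min(here)
        parts$end[k] <- max(here)
      }
    }
    expected <- list(utr5 = i - 1L, cds = j - i + 1L, utr3 = n - j)
  } else {
    expected <- list(utr5 = 0L, cds = 0L, utr3 = 0L)
  }
  list(exons = ex, parts = parts, mature = n, expected = expected,
       coding = coding)
}

# Rows built without exon_rows()/infer_introns(): introns are the gaps
# between transcription-consecutive exons, computed locally.
manual_rows <- function(gene_id, accession, exons, parts = NULL) {
  n <- nrow(exons)
  if (is.null(parts))
    parts <- data.frame(start = rep(NA_integer_, n),
                        end = rep(NA_integer_, n))
  is_minus <- exons$strand[1] == "-"
  intron_s <- intron_e <- rep(NA_integer_, n)
  if (n > 1L) for (i in seq_len(n - 1L)) {
    if (is_minus) {
      intron_s[i] <- exons$end[i + 1L] + 1L
      intron_e[i] <- exons$start[i] - 1L
    } else {
      intron_s[i] <- exons$end[i] + 1L
      intron_e[i] <- exons$start[i + 1L] - 1L
    }
  }
  data.frame(gene_id = gene_id, accession = accession,
             exon_index = seq_len(n), chrom = exons$chrom,
             strand = exons$strand, exon_start = exons$start,
             exon_end = exons$end, cds_start = as.integer(parts$start),
             cds_end = as.integer(parts$end), intron_start = intron_s,
             intron_end = intron_e, exon_seq = NA_character_,
             coding_seq = NA_character_, intron_seq = NA_character_,
             stringsAsFactors = FALSE)
}

toy_gene <- function(gene_id, symbol = gene_id, gene_type = "protein-coding",
                     chrom = "chrT", strand = "+",
                     refseq_status = "REVIEWED",
                     in_current_annotation = TRUE,
                     span_start = NA_integer_, span_end = NA_integer_) {
  data.frame(gene_id = gene_id, symbol = symbol, gene_type = gene_type,
             chrom = chrom, strand = strand, refseq_status = refseq_status,
             in_current_annotation = in_current_annotation,
             span_start = as.integer(span_start),
             span_end = as.integer(span_end), stringsAsFactors = FALSE)
}

toy_tx <- function(accession, gene_id, transcript_status = "REVIEWED") {
  data.frame(accession = accession, gene_id = gene_id,
             transcript_status = transcript_status, stringsAsFactors = FALSE)
}

# summary_stats object -> plain list comparable with a manifest entry
stats_as_list <- function(s, fields) unclass(s)[fields]

SUMMARY_FIELDS <- c("n", "median", "mean", "sd", "total", "min_value",
                    "min_ids", "max_value", "max_ids")

# accession:exon_index ids that stay zero-length for empty tables
rid <- function(df) {
  if (nrow(df)) paste0(df$accession, ":", df$exon_index) else character()
}
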