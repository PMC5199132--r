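#' Construct a genome assembly
#'
#' Holds chromosome sequences and/or lengths. Lengths may exist without
#' sequences: statistics that only need coordinates (everything except
#' sequence extraction and the splice census) work in stats-only mode.
#'
#' @param sequences named character vector of uppercase nucleotide strings,
#'   or `NULL`
#' @param lengths named integer vector of chromosome lengths in bp;
#'   derived from `sequences` when omitted
#' @return an object of class `genome_assembly`
#' @export
genome_assembly <- function(sequences = NULL, lengths = NULL) {
  if (!is.null(sequences)) {
    if (is.null(names(sequences)) || any(!nzchar(names(sequences))))
      stop("sequences must be a named character vector")
    sequences <- toupper(sequences)
    seq_len_ <- vapply(sequences, nchar, integer(1))
    if (is.null(lengths)) lengths <- seq_len_
    else {
      common <- intersect(names(lengths), names(sequences))
      if (any(lengths[common] != seq_len_[common]))
        stop("declared lengths disagree with sequence lengths")
    }
  }
  if (is.null(lengths)) lengths <- integer()
  structure(list(sequences = sequences, lengths = lengths),
            class = "genome_assembly")
}

#' @export
print.genome_assembly <- function(x, ...) {
  cat("genome_assembly:", length(x$lengths), "chromosome(s),",
      format(sum(as.numeric(x$lengths)), big.mark = ","), "bp total",
      if (is.null(x$sequences)) "(lengths only)" else "(sequences loaded)",
      "\n")
  invisible(x)
}

#' Reverse complement of nucleotide strings
#'
#' @param s character vector over A/C/G/T/N (case preserved as uppercase)
#' @return reverse-complemented strings
#' @export
revcomp <- function(s) {
  if (length(s) == 0L) return(character())
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(s)))
}

## internal: resolve an annotation chromosome name against assembly names,
## tolerating a leading "chr" on either side (the most common FASTA vs
## annotation mismatch). Returns NA when no match.
resolve_chrom <- function(name, available, chr_strip = TRUE) {
  hit <- match(name, available)
  if (!chr_strip) return(hit)
  strip <- function(x) sub("^chr", "", x)
  miss <- is.na(hit)
  hit[miss] <- match(strip(name[miss]), strip(available))
  hit
}

#' Extract transcription-oriented sequence for genomic intervals
#'
#' Returns the 1-based inclusive substring `start..end` of the chromosome,
#' reverse-complemented for minus-strand intervals, so the result always
#' reads in transcription orientation and has length `end - start + 1`.
#'
#' @param asm a [genome_assembly()] with sequences loaded
#' @param iv interval data.frame (chrom, start, end, strand)
#' @param chr_strip tolerate a leading `"chr"` mismatch between the
#'   annotation and the assembly (default `TRUE`)
#' @return character vector of sequences, one per interval
#' @export
extract_sequence <- function(asm, iv, chr_strip = TRUE) {
  stopifnot(inherits(asm, "genome_assembly"))
  if (is.null(asm$sequences)) stop("assembly has no sequences loaded")
  if (nrow(iv) == 0L) return(character())
  interval_length(iv)  # validates start <= end
  idx <- resolve_chrom(iv$chrom, names(asm$sequences), chr_strip)
  if (anyNA(idx))
    stop("unknown chromosome(s): ",
         paste(unique(iv$chrom[is.na(idx)]), collapse = ", "))
  clen <- nchar(asm$sequences)[idx]
  over <- iv$end > clen
  if (any(over))
    stop("interval(s) beyond chromosome end: ",
         paste0(iv$chrom[over], ":", iv$start[over], "-", iv$end[over],
                collapse = ", "))
  out <- substring(asm$sequences[idx], iv$start, iv$end)
  minus <- iv$strand == "-"
  if (any(minus)) out[minus] <- revcomp(out[minus])
  unname(out)
}

#' Donor and acceptor dinucleotides of introns
#'
#' The donor is the first two bases and the acceptor the last two bases of
#' the transcription-oriented intron sequence. Introns shorter than 4 bp
#' cannot carry both sites and yield `NA` (they are excluded from the
#' splice census).
#'
#' @param x either a [genome_assembly()] (then `introns` is required) or a
#'   character vector of transcription-oriented intron sequences
#' @param introns interval data.frame of introns, used when `x` is an
#'   assembly
#' @return data.frame with `donor` and `acceptor` columns
#' @export
splice_dinucleotides <- function(x, introns = NULL) {
  seqs <- if (inherits(x, "genome_assembly")) {
    if (is.null(introns)) stop("introns required when passing an assembly")
    extract_sequence(x, introns)
  } else as.character(x)
  n <- nchar(seqs)
  ok <- !is.na(seqs) & n >= 4L
  data.frame(donor = ifelse(ok, substr(seqs, 1L, 2L), NA_character_),
             acceptor = ifelse(ok, substr(seqs, n - 1L, n), NA_character_),
             stringsAsFactors = FALSE)
}

#' The six splice-site categories
#' @export
SPLICE_CATEGORIES <- c("GT-AG", "GC-AG", "AT-AC",
                       "GT-other", "other-AG", "other-other")

#' Classify splice-site dinucleotide pairs
#'
#' The six categories partition all (donor, acceptor) pairs: the canonical
#' GT-AG class, the minor GC-AG and AT-AC classes, the half-canonical
#' GT-other and other-AG classes, and other-other. Pairs containing `N`
#' (assembly gaps) fall in the "other" classes rather than erroring.
#'
#' @param donor,acceptor character vectors of 2-mers over A/C/G/T/N
#' @return character vector of category labels (see [SPLICE_CATEGORIES])
#' @export
classify_splice <- function(donor, acceptor) {
  ifelse(donor == "GT" & acceptor == "AG", "GT-AG",
  ifelse(donor == "GC" & acceptor == "AG", "GC-AG",
  ifelse(donor == "AT" & acceptor == "AC", "AT-AC",
  ifelse(donor == "GT", "GT-other",
  ifelse(acceptor == "AG", "other-AG", "other-other")))))
}

#' Attach exon, coding and intron sequences to annotation rows
#'
#' Populates `exon_seq`, `coding_seq` and `intron_seq` (transcription
#' orientation) for the rows selected by `select`; unselected rows remain
#' sequence-free. Sequence work is typically restricted to the curated
#' NM_/NR_ rows, which is what [curated_subset()] selects. Chromosome
#' availability is checked before any mutation.
#'
#' @param x an `annotation_set`
#' @param asm a [genome_assembly()] with sequences
#' @param select logical vector over `x$rows`, or `NULL` for all rows
#' @param chr_strip see [extract_sequence()]
#' @return `x` with sequence columns populated on the selected rows
#' @export
attach_sequences <- function(x, asm, select = NULL, chr_strip = TRUE) {
  stopifnot(inherits(x, "annotation_set"))
  rows <- x$rows
  if (is.null(select)) select <- rep(TRUE, nrow(rows))
  sel <- which(select)
  if (length(sel) == 0L) return(x)
  need <- unique(rows$chrom[sel])
  idx <- resolve_chrom(need, names(asm$sequences), chr_strip)
  if (anyNA(idx))
    stop("assembly lacks chromosome(s): ",
         paste(need[is.na(idx)], collapse = ", "))
  r <- rows[sel, , drop = FALSE]
  rows$exon_seq[sel] <- extract_sequence(asm, data.frame(
    chrom = r$chrom, start = r$exon_start, end = r$exon_end,
    strand = r$strand), chr_strip)
  has_cds <- sel[!is.na(r$cds_start)]
  if (length(has_cds)) {
    rc <- rows[has_cds, , drop = FALSE]
    rows$coding_seq[has_cds] <- extract_sequence(asm, data.frame(
      chrom = rc$chrom, start = rc$cds_start, end = rc$cds_end,
      strand = rc$strand), chr_strip)
  }
  has_int <- sel[!is.na(r$intron_start)]
  if (length(has_int)) {
    ri <- rows[has_int, , drop = FALSE]
    rows$intron_seq[has_int] <- extract_sequence(asm, data.frame(
      chrom = ri$chrom, start = ri$intron_start, end = ri$intron_end,
      strand = ri$strand), chr_strip)
  }
  x$rows <- rows
  x
}
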