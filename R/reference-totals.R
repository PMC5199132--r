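#' Published reference totals for the human nuclear gene set
#'
#' Printed aggregate totals from a published survey of the curated human
#' nuclear gene set (NCBI Gene annotation, January 2016 snapshot, GRCh38):
#' total chromosome length, total protein-coding and non-coding gene
#' lengths, non-redundant exon and coding-exon totals, the splice-site
#' census of the available intron sequences, and the curated gene and
#' transcript counts. These constants are the inputs to
#' [check_human_fractions()], which re-derives the survey's headline
#' percentages from them.
#'
#' @return named numeric vector of totals (bp, Mb or counts as named)
#' @examples
#' human_gene_totals()[["pc_gene_total_bp"]]
#' @export
human_gene_totals <- function() {
  c(genome_total_mb = 3088.27,
    genome_total_bp = 3088.27 * 1e6,
    pc_gene_total_bp = 1215363666,
    nc_gene_total_bp = 141838888,
    nr_exon_total_bp = 53827863,
    nr_coding_exon_total_bp = 23698355,
    introns_classified = 414385,
    introns_gtag = 410038,
    introns_gcag = 3594,
    introns_atac = 439,
    genes_total = 22451,
    genes_multi_isoform = 14944,
    transcripts_total = 45541,
    transcripts_intronless_pc = 554,
    transcripts_intronless_nc = 948)
}

#' Re-derive the published human percentages from the printed totals
#'
#' Computes twelve headline percentages of the human gene-structure survey
#' from the published totals ([human_gene_totals()]): genome fractions of
#' protein-coding, non-coding and all genes; the mature-mRNA share of gene
#' DNA; exon and strict-sense coding fractions of the genome; the coding
#' share of exon sequence; the intronless-transcript and multi-isoform
#' shares; and the three splice-census shares. Each computed value is
#' compared, after half-up rounding to the printed precision, with the
#' published figure.
#'
#' @param totals named numeric vector as returned by [human_gene_totals()]
#' @return data.frame with columns `name`, `numerator`, `denominator`,
#'   `computed` (full precision percentage), `digits` (printed decimal
#'   places), `rounded`, `published`, `pass`
#' @export
check_human_fractions <- function(totals = human_gene_totals()) {
  t <- as.list(totals)
  row <- function(name, num, den, digits, published) {
    pct <- 100 * num / den
    data.frame(name = name, numerator = num, denominator = den,
               computed = pct, digits = digits,
               rounded = round_half_up(pct, digits), published = published,
               stringsAsFactors = FALSE)
  }
  out <- rbind(
    row("pc_gene_pct_of_genome", t$pc_gene_total_bp, t$genome_total_bp,
        2, 39.35),
    row("nc_gene_pct_of_genome", t$nc_gene_total_bp, t$genome_total_bp,
        2, 4.59),
    row("genic_pct_of_genome", t$pc_gene_total_bp + t$nc_gene_total_bp,
        t$genome_total_bp, 2, 43.95),
    row("exon_pct_of_gene_dna", t$nr_exon_total_bp, t$pc_gene_total_bp,
        2, 4.43),
    row("exon_pct_of_genome", t$nr_exon_total_bp, t$genome_total_bp,
        2, 1.74),
    row("coding_pct_of_exons", t$nr_coding_exon_total_bp,
        t$nr_exon_total_bp, 2, 44.03),
    row("coding_pct_of_genome", t$nr_coding_exon_total_bp,
        t$genome_total_bp, 2, 0.77),
    row("intronless_transcript_pct",
        t$transcripts_intronless_pc + t$transcripts_intronless_nc,
        t$transcripts_total, 1, 3.3),
    row("multi_isoform_gene_pct", t$genes_multi_isoform, t$genes_total,
        2, 66.56),
    row("splice_gtag_pct", t$introns_gtag, t$introns_classified, 2, 98.95),
    row("splice_gcag_pct", t$introns_gcag, t$introns_classified, 2, 0.87),
    row("splice_atac_pct", t$introns_atac, t$introns_classified, 2, 0.11))
  out$pass <- out$rounded == out$published
  rownames(out) <- NULL
  out
}
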