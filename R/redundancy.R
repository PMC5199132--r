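#' Non-redundant exon, coding-exon or intron set
#'
#' Collapses features shared across transcript isoforms: two occurrences
#' collapse iff they have identical `(chrom, strand, start, end)`
#' coordinates of, respectively, the exon, the coding part of the exon, or
#' the downstream intron. Coding exons are keyed on the coding subinterval,
#' not the whole exon, so isoforms sharing an exon but differing in CDS
#' start contribute two distinct coding-exon members. Collapsing is
#' genome-wide: identical intervals claimed by two genes collapse once and
#' the provenance lists both.
#'
#' @param rows the `rows` table of an annotation set (or any subset of it)
#' @param kind `"exon"`, `"coding_exon"` or `"intron"`
#' @return a data.frame of class `nonredundant_set` with columns `chrom`,
#'   `start`, `end`, `strand`, `multiplicity` (occurrence count) and
#'   `provenance` (comma-separated `accession:exon_index` contributors),
#'   sorted by (chrom, start, end, strand). The `kind` and the number of
#'   redundant occurrences are attached as attributes.
#' @export
nonredundant_set <- function(rows, kind = c("exon", "coding_exon", "intron")) {
  kind <- match.arg(kind)
  cols <- switch(kind,
                 exon = c("exon_start", "exon_end"),
                 coding_exon = c("cds_start", "cds_end"),
                 intron = c("intron_start", "intron_end"))
  keep <- !is.na(rows[[cols[1]]]) & !is.na(rows[[cols[2]]])
  r <- rows[keep, , drop = FALSE]
  if (nrow(r) == 0L) {
    out <- data.frame(chrom = character(), start = integer(), end = integer(),
                      strand = character(), multiplicity = integer(),
                      provenance = character(), stringsAsFactors = FALSE)
    attr(out, "kind") <- kind
    attr(out, "n_redundant") <- 0L
    class(out) <- c("nonredundant_set", class(out))
    return(out)
  }
  key <- paste(r$chrom, r$strand, r[[cols[1]]], r[[cols[2]]], sep = "\r")
  prov <- paste0(r$accession, ":", r$exon_index)
  first <- !duplicated(key)
  mult <- as.integer(table(key)[key[first]])
  provenance <- vapply(split(prov, key)[key[first]],
                       function(p) paste(sort(p), collapse = ","), "")
  out <- data.frame(chrom = r$chrom[first],
                    start = r[[cols[1]]][first],
                    end = r[[cols[2]]][first],
                    strand = r$strand[first],
                    multiplicity = mult,
                    provenance = unname(provenance),
                    stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$start, out$end, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "kind") <- kind
  attr(out, "n_redundant") <- nrow(r)
  class(out) <- c("nonredundant_set", class(out))
  out
}

#' @export
print.nonredundant_set <- function(x, ...) {
  cat("non-redundant", attr(x, "kind"), "set:", nrow(x), "members from",
      attr(x, "n_redundant"), "occurrences\n")
  NextMethod()
}
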