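## Deterministic synthetic genome + annotation generator. The generator
## builds transcripts in transcript space first (so mature/CDS/UTR lengths
## and the isoform-sharing structure are known by construction), then maps
## them onto synthetic chromosomes and writes the planted splice-site
## dinucleotides into the genome sequence. Its truth manifest is computed
## with generator-local code during construction, never by running the
## analysis pipeline, so tests compare two independent routes.

#' Specification for a synthetic annotation fixture
#'
#' Defaults emulate the statistical structure of a curated multi-isoform
#' gene set at desk scale: ~200 genes across 3 chromosomes, a majority of
#' protein-coding genes, 1-8 isoforms per gene sharing most internal
#' exons, 2-12 exons per transcript with a small monoexonic fraction, and
#' a splice-site class mix dominated by the canonical GT-AG configuration.
#' tRNA genes (and a small random fraction of others) are emitted as
#' transcript-less records carrying only a genomic span.
#'
#' @param seed integer seed; identical specs generate identical fixtures
#' @param n_genes number of genes
#' @param n_chroms number of chromosomes (genes assigned round-robin)
#' @param gene_type_freq named frequencies over the gene-type vocabulary
#' @param gene_status_freq,tx_status_freq named frequencies over RefSeq
#'   statuses for genes and transcripts
#' @param p_not_in_current probability a gene is flagged as not in the
#'   current annotation release
#' @param p_transcriptless probability a (non-tRNA) gene has no
#'   transcripts, only an annotated span; tRNA genes are always
#'   transcript-less
#' @param isoform_freq frequencies of 1, 2, ... isoforms per gene
#' @param exons_per_tx_range inclusive range of exon counts for
#'   multi-exon transcripts
#' @param p_monoexonic probability a gene's transcript template has a
#'   single exon
#' @param exon_len_range,intron_len_range,utr_len_range inclusive bp
#'   ranges
#' @param p_keep_exon probability an alternative isoform keeps each
#'   template exon (drives exon/intron sharing across isoforms)
#' @param p_alt_boundary probability an alternative isoform shifts its
#'   transcription-start boundary (creates near-duplicate exons)
#' @param splice_freq named frequencies over the six splice categories;
#'   categories are apportioned to introns deterministically (largest
#'   remainder), so planted class counts are exact up to boundary overlap
#'   between isoforms
#' @param n_motif_introns number of canonical introns whose acceptor end
#'   is overwritten with `motif` (for sequence-predicate queries)
#' @param motif intron 3'-suffix motif to plant (must end with `AG`)
#' @param intergenic_gap_range inclusive bp range between gene loci
#' @param plant_anomalies plant three QC anomalies (a 29 bp intron, a
#'   1 bp exon, and a coding transcript with a 0 bp 5' UTR) in the first
#'   three genes
#' @return an object of class `fixture_spec`
#' @export
fixture_spec <- function(seed = 1L,
                         n_genes = 200L,
                         n_chroms = 3L,
                         gene_type_freq = c("protein-coding" = 0.55,
                                            pseudo = 0.06, ncRNA = 0.14,
                                            snoRNA = 0.03, snRNA = 0.02,
                                            rRNA = 0.02, tRNA = 0.08,
                                            other = 0.05, unknown = 0.05),
                         gene_status_freq = c(REVIEWED = 0.35,
                                              VALIDATED = 0.30,
                                              PROVISIONAL = 0.20,
                                              PREDICTED = 0.03,
                                              INFERRED = 0.02,
                                              MODEL = 0.10),
                         tx_status_freq = c(REVIEWED = 0.40,
                                            VALIDATED = 0.30,
                                            PROVISIONAL = 0.15,
                                            MODEL = 0.15),
                         p_not_in_current = 0.05,
                         p_transcriptless = 0.05,
                         isoform_freq = c(0.25, 0.20, 0.18, 0.13, 0.10,
                                          0.07, 0.04, 0.03),
                         exons_per_tx_range = c(2L, 12L),
                         p_monoexonic = 0.05,
                         exon_len_range = c(40L, 400L),
                         intron_len_range = c(50L, 1500L),
                         utr_len_range = c(10L, 150L),
                         p_keep_exon = 0.75,
                         p_alt_boundary = 0.35,
                         splice_freq = c("GT-AG" = 0.90, "GC-AG" = 0.04,
                                         "AT-AC" = 0.02, "GT-other" = 0.02,
                                         "other-AG" = 0.01,
                                         "other-other" = 0.01),
                         n_motif_introns = 2L,
                         motif = "CAGCAG",
                         intergenic_gap_range = c(200L, 800L),
                         plant_anomalies = FALSE) {
  norm <- function(f) {
    if (any(f < 0) || sum(f) <= 0) stop("frequencies must be non-negative ",
                                        "and sum to a positive value")
    f / sum(f)
  }
  chk_range <- function(r, lo, what) {
    if (length(r) != 2L || r[1] > r[2] || r[1] < lo)
      stop("infeasible ", what, " range")
    as.integer(r)
  }
  spec <- list(
    seed = as.integer(seed), n_genes = as.integer(n_genes),
    n_chroms = as.integer(n_chroms),
    gene_type_freq = norm(gene_type_freq[GENE_TYPES[GENE_TYPES %in%
                                                    names(gene_type_freq)]]),
    gene_status_freq = norm(gene_status_freq),
    tx_status_freq = norm(tx_status_freq),
    p_not_in_current = p_not_in_current,
    p_transcriptless = p_transcriptless,
    isoform_freq = norm(isoform_freq),
    exons_per_tx_range = chk_range(exons_per_tx_range, 1L, "exon count"),
    p_monoexonic = p_monoexonic,
    exon_len_range = chk_range(exon_len_range, 2L, "exon length"),
    intron_len_range = chk_range(intron_len_range, 30L, "intron length"),
    utr_len_range = chk_range(utr_len_range, 1L, "UTR length"),
    p_keep_exon = p_keep_exon, p_alt_boundary = p_alt_boundary,
    splice_freq = norm(splice_freq[SPLICE_CATEGORIES]),
    n_motif_introns = as.integer(n_motif_introns), motif = motif,
    intergenic_gap_range = chk_range(intergenic_gap_range, 10L,
                                     "intergenic gap"),
    plant_anomalies = isTRUE(plant_anomalies))
  if (!endsWith(spec$motif, "AG"))
    stop("motif must end with AG (it replaces a canonical acceptor end)")
  if (anyNA(spec$splice_freq)) stop("splice_freq must cover all six ",
                                    "categories")
  class(spec) <- "fixture_spec"
  spec
}

## ---- generator-local helpers (kept independent of the pipeline code) ----

rint <- function(lo, hi) lo + sample.int(hi - lo + 1L, 1L) - 1L
rpick <- function(freq) sample(names(freq), 1L, prob = freq)

FX_COMP <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

fx_seq <- function(chars, s, e, strand) {
  b <- chars[s:e]
  if (strand == "-") b <- rev(unname(FX_COMP[b]))
  paste(b, collapse = "")
}

fx_classify <- function(donor, acceptor) {
  if (donor == "GT" && acceptor == "AG") return("GT-AG")
  if (donor == "GC" && acceptor == "AG") return("GC-AG")
  if (donor == "AT" && acceptor == "AC") return("AT-AC")
  if (donor == "GT") return("GT-other")
  if (acceptor == "AG") return("other-AG")
  "other-other"
}

fx_summary <- function(v, ids) {
  v <- as.numeric(v)
  n <- length(v)
  if (n == 0L)
    return(list(n = 0L, median = NA_real_, mean = NA_real_, sd = NA_real_,
                total = NA_real_, min_value = NA_real_,
                min_ids = character(), max_value = NA_real_,
                max_ids = character()))
  sv <- sort(v)
  med <- if (n %% 2L == 1L) sv[(n + 1L) / 2L] else
    (sv[n / 2L] + sv[n / 2L + 1L]) / 2
  sdv <- if (n > 1L) sqrt(sum((v - mean(v))^2) / (n - 1L)) else NA_real_
  list(n = n, median = med, mean = sum(v) / n, sd = sdv, total = sum(v),
       min_value = min(v), min_ids = sort(unique(ids[v == min(v)])),
       max_value = max(v), max_ids = sort(unique(ids[v == max(v)])))
}

fx_nr <- function(rows, scol, ecol) {
  keep <- !is.na(rows[[scol]])
  r <- rows[keep, , drop = FALSE]
  key <- paste(r$chrom, r$strand, r[[scol]], r[[ecol]])
  u <- !duplicated(key)
  list(n = sum(u),
       total_bp = sum(r[[ecol]][u] - r[[scol]][u] + 1L),
       n_redundant = nrow(r))
}

## deterministic apportionment of n items to categories (largest remainder)
fx_apportion <- function(freq, n) {
  raw <- freq * n
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

## map a transcript-space CDS (utr5, cds_len) onto per-exon genomic parts
fx_map_cds <- function(exons, strand, utr5, cds_len) {
  lens <- exons$end - exons$start + 1L
  off <- cumsum(c(0L, lens))
  c1 <- utr5 + 1L; c2 <- utr5 + cds_len
  ps <- pe <- rep(NA_integer_, nrow(exons))
  for (i in seq_len(nrow(exons))) {
    a <- off[i] + 1L; b <- off[i] + lens[i]
    s <- max(a, c1); e <- min(b, c2)
    if (s > e) next
    if (strand == "+") {
      ps[i] <- exons$start[i] + (s - a); pe[i] <- exons$start[i] + (e - a)
    } else {
      pe[i] <- exons$end[i] - (s - a); ps[i] <- exons$end[i] - (e - a)
    }
  }
  data.frame(start = ps, end = pe)
}

#' Generate a synthetic annotation fixture with a truth manifest
#'
#' Builds a deterministic synthetic genome, annotation set and truth
#' manifest from a [fixture_spec()]. The manifest holds the exact
#' per-transcript and per-gene features, the curated-subset membership,
#' non-redundant set sizes and totals, the splice census (recomputed from
#' the final genome sequence with generator-local code, so boundary
#' overlaps between isoforms cannot desynchronize it), the planted
#' motif-carrying rows, and reference summary statistics for the curated
#' subset — everything the analysis pipeline should reproduce.
#'
#' @param spec a [fixture_spec()]
#' @return a list of class `gene_fixture` with elements `spec`,
#'   `annotation` (an [annotation_set()]), `assembly` (a
#'   [genome_assembly()]) and `manifest`
#' @export
make_fixture <- function(spec = fixture_spec()) {
  stopifnot(inherits(spec, "fixture_spec"))
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old_seed <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(spec$seed)

  chroms <- paste0("chr", seq_len(spec$n_chroms))
  cursor <- stats::setNames(rep(0L, spec$n_chroms), chroms)
  genes_l <- list(); tx_l <- list(); rows_l <- list(); feat_l <- list()
  acc_counter <- 0L

  for (gi in seq_len(spec$n_genes)) {
    gene_id <- sprintf("G%05d", gi)
    symbol <- sprintf("SYM%05d", gi)
    chrom <- chroms[((gi - 1L) %% spec$n_chroms) + 1L]
    strand <- sample(c("+", "-"), 1L)
    anomaly <- if (spec$plant_anomalies && gi <= 3L) gi else 0L

    if (anomaly) {
      gene_type <- if (anomaly == 3L) "protein-coding" else "ncRNA"
      gene_status <- "REVIEWED"; in_current <- TRUE
    } else {
      gene_type <- rpick(spec$gene_type_freq)
      gene_status <- rpick(spec$gene_status_freq)
      in_current <- stats::runif(1) >= spec$p_not_in_current
    }
    gap <- rint(spec$intergenic_gap_range[1], spec$intergenic_gap_range[2])
    origin <- cursor[[chrom]] + gap

    transcriptless <- !anomaly &&
      (gene_type == "tRNA" || stats::runif(1) < spec$p_transcriptless)
    if (transcriptless) {
      span_len <- rint(60L, 300L)
      genes_l[[gi]] <- data.frame(
        gene_id = gene_id, symbol = symbol, gene_type = gene_type,
        chrom = chrom, strand = strand, refseq_status = gene_status,
        in_current_annotation = in_current,
        span_start = origin, span_end = origin + span_len - 1L,
        stringsAsFactors = FALSE)
      cursor[[chrom]] <- origin + span_len - 1L
      next
    }

    ## template exon chain (local coordinates starting at 1)
    if (anomaly == 1L) {
      m <- 2L; elens <- c(100L, 100L); ilens <- 29L
    } else if (anomaly == 2L) {
      m <- 3L; elens <- c(100L, 1L, 100L); ilens <- c(60L, 60L)
    } else if (anomaly == 3L) {
      m <- 2L; elens <- c(150L, 200L); ilens <- 80L
    } else {
      m <- if (stats::runif(1) < spec$p_monoexonic) 1L else
        rint(max(2L, spec$exons_per_tx_range[1]), spec$exons_per_tx_range[2])
      elens <- vapply(seq_len(m), function(i)
        rint(spec$exon_len_range[1], spec$exon_len_range[2]), integer(1))
      ilens <- if (m > 1L) vapply(seq_len(m - 1L), function(i)
        rint(spec$intron_len_range[1], spec$intron_len_range[2]),
        integer(1)) else integer()
    }
    estart <- cumsum(c(1L, utils::head(elens, -1L) + ilens))
    template <- data.frame(start = estart, end = estart + elens - 1L)

    n_iso <- if (anomaly) 1L else
      sample.int(length(spec$isoform_freq), 1L, prob = spec$isoform_freq)

    for (k in seq_len(n_iso)) {
      keep <- if (k == 1L) rep(TRUE, m) else
        stats::runif(m) < spec$p_keep_exon
      if (!any(keep)) keep[sample.int(m, 1L)] <- TRUE
      ex <- template[keep, , drop = FALSE]
      if (k > 1L && stats::runif(1) < spec$p_alt_boundary) {
        ## shift the transcription-start boundary inward a little
        j <- if (strand == "+") 1L else nrow(ex)
        if (ex$end[j] - ex$start[j] + 1L > 25L) {
          d <- rint(1L, 15L)
          if (strand == "+") ex$start[j] <- ex$start[j] + d
          else ex$end[j] <- ex$end[j] - d
        }
      }
      tx_status <- if (anomaly) "REVIEWED" else rpick(spec$tx_status_freq)
      coding <- gene_type == "protein-coding"
      prefix <- if (coding) {
        if (tx_status == "MODEL") "XM_" else "NM_"
      } else {
        if (tx_status == "MODEL") "XR_" else "NR_"
      }
      acc_counter <- acc_counter + 1L
      accession <- sprintf("%s%06d", prefix, acc_counter)

      mature <- sum(ex$end - ex$start + 1L)
      if (coding) {
        if (anomaly == 3L) {
          utr5 <- 0L; utr3 <- 50L; cds <- mature - 50L  # 300, %% 3 == 0
        } else {
          utr5 <- rint(spec$utr_len_range[1], spec$utr_len_range[2])
          utr3 <- rint(spec$utr_len_range[1], spec$utr_len_range[2])
          max_utr <- mature - 9L
          if (utr5 + utr3 > max_utr) {
            u5 <- max(1L, (max_utr * utr5) %/% (utr5 + utr3))
            utr3 <- max(1L, max_utr - u5)
            utr5 <- max_utr - utr3
          }
          cds <- mature - utr5 - utr3
          rem <- cds %% 3L
          utr3 <- utr3 + rem
          cds <- cds - rem
        }
        parts <- fx_map_cds(
          if (strand == "+") ex else ex[rev(seq_len(nrow(ex))), ,
                                        drop = FALSE],
          strand, utr5, cds)
        n_coding <- sum(!is.na(parts$start))
      } else {
        utr5 <- utr3 <- cds <- 0L
        parts <- data.frame(start = rep(NA_integer_, nrow(ex)),
                            end = rep(NA_integer_, nrow(ex)))
        n_coding <- 0L
      }

      ## rows in transcription order, with local coordinates for now
      ex_tx <- if (strand == "+") ex else
        ex[rev(seq_len(nrow(ex))), , drop = FALSE]
      nk <- nrow(ex_tx)
      intron_s <- intron_e <- rep(NA_integer_, nk)
      if (nk > 1L) {
        for (i in seq_len(nk - 1L)) {
          if (strand == "+") {
            intron_s[i] <- ex_tx$end[i] + 1L
            intron_e[i] <- ex_tx$start[i + 1L] - 1L
          } else {
            intron_s[i] <- ex_tx$end[i + 1L] + 1L
            intron_e[i] <- ex_tx$start[i] - 1L
          }
        }
      }
      rows_l[[length(rows_l) + 1L]] <- data.frame(
        gene_id = gene_id, accession = accession, exon_index = seq_len(nk),
        chrom = chrom, strand = strand,
        exon_start = ex_tx$start + origin - 1L,
        exon_end = ex_tx$end + origin - 1L,
        cds_start = parts$start + origin - 1L,
        cds_end = parts$end + origin - 1L,
        intron_start = intron_s + origin - 1L,
        intron_end = intron_e + origin - 1L,
        stringsAsFactors = FALSE)
      tx_l[[length(tx_l) + 1L]] <- data.frame(
        accession = accession, gene_id = gene_id,
        transcript_status = tx_status, stringsAsFactors = FALSE)
      feat_l[[length(feat_l) + 1L]] <- data.frame(
        accession = accession, gene_id = gene_id, mature_len = mature,
        cds_len = cds, utr5_len = utr5, utr3_len = utr3, n_exons = nk,
        n_coding_exons = n_coding, n_introns = nk - 1L,
        is_monoexonic = nk == 1L, stringsAsFactors = FALSE)
    }

    locus_len <- max(template$end)
    genes_l[[gi]] <- data.frame(
      gene_id = gene_id, symbol = symbol, gene_type = gene_type,
      chrom = chrom, strand = strand, refseq_status = gene_status,
      in_current_annotation = in_current,
      span_start = origin, span_end = origin + locus_len - 1L,
      stringsAsFactors = FALSE)
    cursor[[chrom]] <- origin + locus_len - 1L
  }

  genes <- do.call(rbind, genes_l)
  transcripts <- if (length(tx_l)) do.call(rbind, tx_l) else
    empty_transcripts()
  rows <- if (length(rows_l)) do.call(rbind, rows_l) else empty_rows()
  feats <- if (length(feat_l)) do.call(rbind, feat_l) else NULL

  ## ---- genome sequence with planted splice dinucleotides ----
  chrom_len <- cursor + 200L
  chars <- lapply(chrom_len, function(L)
    sample(c("A", "C", "G", "T"), L, replace = TRUE))

  with_intron <- !is.na(rows$intron_start)
  ikey <- paste(rows$chrom, rows$strand, rows$intron_start,
                rows$intron_end)[with_intron]
  uniq <- !duplicated(ikey)
  ui <- rows[with_intron, , drop = FALSE][uniq, , drop = FALSE]
  n_ui <- nrow(ui)
  if (n_ui > 0L) {
    counts <- fx_apportion(spec$splice_freq, n_ui)
    cats <- sample(rep(SPLICE_CATEGORIES, counts))
    donors_other <- c("AA", "CT", "TT", "CA")
    accept_other <- c("CC", "TT", "GG")
    for (i in seq_len(n_ui)) {
      da <- switch(cats[i],
        "GT-AG" = c("GT", "AG"), "GC-AG" = c("GC", "AG"),
        "AT-AC" = c("AT", "AC"),
        "GT-other" = c("GT", sample(accept_other, 1L)),
        "other-AG" = c(sample(donors_other, 1L), "AG"),
        "other-other" = c(sample(donors_other, 1L),
                          sample(accept_other, 1L)))
      s <- ui$intron_start[i]; e <- ui$intron_end[i]; ch <- ui$chrom[i]
      d <- strsplit(da[1], "")[[1]]; a <- strsplit(da[2], "")[[1]]
      if (ui$strand[i] == "+") {
        chars[[ch]][c(s, s + 1L)] <- d
        chars[[ch]][c(e - 1L, e)] <- a
      } else {
        chars[[ch]][c(e, e - 1L)] <- unname(FX_COMP[d])
        chars[[ch]][c(s + 1L, s)] <- unname(FX_COMP[a])
      }
    }
    ## plant the acceptor-end motif on canonical introns long enough
    mlen <- nchar(spec$motif)
    eligible <- which(cats == "GT-AG" &
                        (ui$intron_end - ui$intron_start + 1L) >= mlen + 4L)
    planted <- utils::head(eligible, spec$n_motif_introns)
    mb <- strsplit(spec$motif, "")[[1]]
    for (i in planted) {
      s <- ui$intron_start[i]; e <- ui$intron_end[i]; ch <- ui$chrom[i]
      if (ui$strand[i] == "+") chars[[ch]][(e - mlen + 1L):e] <- mb
      else chars[[ch]][s:(s + mlen - 1L)] <- rev(unname(FX_COMP[mb]))
    }
  }

  ## ---- manifest (generator-local computations) ----
  good_status <- c("REVIEWED", "VALIDATED")
  tx_rv <- unique(transcripts$gene_id[
    transcripts$transcript_status %in% good_status])
  cur_genes <- genes$gene_id[genes$refseq_status %in% good_status &
                               genes$in_current_annotation &
                               genes$gene_id %in% tx_rv]
  cur_acc <- transcripts$accession[
    transcripts$gene_id %in% cur_genes &
      substr(transcripts$accession, 1L, 1L) == "N"]
  cur_rows <- rows[rows$accession %in% cur_acc, , drop = FALSE]
  cur_feats <- feats[feats$accession %in% cur_acc, , drop = FALSE]

  ## per-gene features over the curated transcripts (mirrors how the
  ## curated annotation set is summarized)
  gene_feats_local <- function(gene_ids, acc_subset) {
    do.call(rbind, lapply(gene_ids, function(g) {
      acc <- intersect(acc_subset,
                       transcripts$accession[transcripts$gene_id == g])
      r <- rows[rows$accession %in% acc, , drop = FALSE]
      f <- feats[feats$accession %in% acc, , drop = FALSE]
      f <- f[order(-f$n_exons, f$accession), , drop = FALSE]
      data.frame(gene_id = g,
                 gene_len = if (nrow(r))
                   max(r$exon_end) - min(r$exon_start) + 1L else NA_integer_,
                 n_transcripts = length(acc),
                 max_exons = if (nrow(f)) f$n_exons[1] else NA_integer_,
                 max_coding_exons = if (nrow(f)) f$n_coding_exons[1] else
                   NA_integer_,
                 stringsAsFactors = FALSE)
    }))
  }
  cur_gf <- gene_feats_local(sort(cur_genes), cur_acc)

  ## splice census + motif hits re-extracted from the final genome
  census <- stats::setNames(rep(0L, length(SPLICE_CATEGORIES)),
                            SPLICE_CATEGORIES)
  motif_rows <- character()
  wi <- which(!is.na(rows$intron_start))
  for (i in wi) {
    s <- rows$intron_start[i]; e <- rows$intron_end[i]
    if (e - s + 1L < 4L) next
    sq <- fx_seq(chars[[rows$chrom[i]]], s, e, rows$strand[i])
    cat_i <- fx_classify(substr(sq, 1L, 2L),
                         substr(sq, nchar(sq) - 1L, nchar(sq)))
    census[[cat_i]] <- census[[cat_i]] + 1L
    if (endsWith(sq, spec$motif))
      motif_rows <- c(motif_rows,
                      paste0(rows$accession[i], ":", rows$exon_index[i]))
  }

  cur_ids <- paste0(cur_rows$accession, ":", cur_rows$exon_index)
  manifest <- list(
    counts = list(n_genes = nrow(genes), n_transcripts = nrow(transcripts),
                  n_rows = nrow(rows)),
    transcript_features = feats,
    gene_features_curated = cur_gf,
    curated = list(gene_ids = sort(cur_genes), accessions = sort(cur_acc)),
    nonredundant = list(
      all = list(exon = fx_nr(rows, "exon_start", "exon_end"),
                 coding_exon = fx_nr(rows, "cds_start", "cds_end"),
                 intron = fx_nr(rows, "intron_start", "intron_end")),
      curated = list(exon = fx_nr(cur_rows, "exon_start", "exon_end"),
                     coding_exon = fx_nr(cur_rows, "cds_start", "cds_end"),
                     intron = fx_nr(cur_rows, "intron_start",
                                    "intron_end"))),
    splice_census = as.list(census),
    motif = spec$motif,
    motif_rows = sort(motif_rows),
    summaries = list(
      mature_len = fx_summary(cur_feats$mature_len, cur_feats$accession),
      cds_len = fx_summary(cur_feats$cds_len, cur_feats$accession),
      utr5_len = fx_summary(cur_feats$utr5_len, cur_feats$accession),
      utr3_len = fx_summary(cur_feats$utr3_len, cur_feats$accession),
      n_exons = fx_summary(cur_feats$n_exons, cur_feats$accession),
      gene_len = fx_summary(cur_gf$gene_len, cur_gf$gene_id),
      n_transcripts = fx_summary(cur_gf$n_transcripts, cur_gf$gene_id),
      exon_len = fx_summary(cur_rows$exon_end - cur_rows$exon_start + 1L,
                            cur_ids),
      intron_len = {
        has <- !is.na(cur_rows$intron_start)
        fx_summary(cur_rows$intron_end[has] - cur_rows$intron_start[has]
                   + 1L, cur_ids[has])
      }))

  seqs <- vapply(chars, paste, character(1), collapse = "")
  assembly <- genome_assembly(sequences = seqs)
  annotation <- annotation_set(
    genes = genes, transcripts = transcripts, rows = rows,
    provenance = sprintf("fixture seed=%d n_genes=%d", spec$seed,
                         spec$n_genes))
  structure(list(spec = spec, annotation = annotation, assembly = assembly,
                 manifest = manifest), class = "gene_fixture")
}

#' Write a fixture to disk
#'
#' Emits `genome.fa`, `annotation.gff3`, the native three-table dialect
#' and `truth_manifest.json`. Byte-identical across runs for the same
#' spec.
#'
#' @param fx a fixture from [make_fixture()]
#' @param out_dir output directory (created if needed)
#' @return named vector of written paths, invisibly
#' @export
write_fixture <- function(fx, out_dir) {
  stopifnot(inherits(fx, "gene_fixture"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(out_dir, "genome.fa")
  gff <- file.path(out_dir, "annotation.gff3")
  man <- file.path(out_dir, "truth_manifest.json")
  write_fasta(fx$assembly, fa)
  write_gff3(fx$annotation, gff, fx$assembly)
  tabs <- write_tables(fx$annotation, out_dir)
  jsonlite::write_json(fx$manifest, man, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(c(genome = fa, gff3 = gff, tabs, manifest = man))
}
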