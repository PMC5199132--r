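test_that("filters select by status, prefix, range and sequence suffix", {
  df <- data.frame(
    id = paste0("r", 1:5),
    refseq_status = c("REVIEWED", "MODEL", "VALIDATED", "REVIEWED",
                      "PREDICTED"),
    accession = c("NM_1", "XM_123", "NM_2", "NR_3", "XR_4"),
    len = c(10, 20, 30, 40, 50),
    intron_seq = c("GTACAGCAG", "GTAAAG", "TTCAGCAG", "GTAAAT", NA),
    stringsAsFactors = FALSE)
  s1 <- apply_filter(df, filter_spec(
    flt_in("refseq_status", c("REVIEWED", "VALIDATED"))))
  expect_identical(s1$id, c("r1", "r3", "r4"))
  s2 <- apply_filter(df, filter_spec(flt_prefix("accession", "NM_")))
  expect_identical(s2$accession, c("NM_1", "NM_2"))
  expect_false("XM_123" %in% s2$accession)
  s3 <- apply_filter(df, filter_spec(flt_suffix("intron_seq", "CAGCAG")))
  expect_identical(s3$id, c("r1", "r3"))
  s4 <- apply_filter(df, filter_spec(flt_range("len", 15, 45)))
  expect_identical(nrow(s4), 3L)
  expect_error(apply_filter(df, filter_spec(flt_equals("nope", 1))),
               "unknown field")
})

test_that("filter specs parse from JSON and adding clauses only shrinks", {
  spec <- parse_filter_spec(
    '[{"op":"prefix","field":"accession","value":"NM_"},
      {"op":"range","field":"len","lo":15}]')
  df <- data.frame(accession = c("NM_1", "NM_2", "NR_3"),
                   len = c(10, 30, 99), stringsAsFactors = FALSE)
  expect_identical(apply_filter(df, spec)$accession, "NM_2")
  set.seed(21)
  fx <- make_fixture(fixture_spec(seed = 21, n_genes = 20))
  rows <- row_features(fx$annotation)
  clauses <- list(flt_range("exon_len", 50, 300),
                  flt_prefix("accession", "N"),
                  flt_in("position_class", c("internal", "last")))
  sub <- rows
  for (k in seq_along(clauses)) {
    nxt <- apply_filter(rows, filter_spec(clauses[seq_len(k)]))
    expect_lte(nrow(nxt), nrow(sub))
    sub <- nxt
  }
})

test_that("summary statistics use midpoint median, sample SD and tie ids", {
  s <- summary_stats(c(1, 2, 3), c("a", "b", "c"))
  expect_identical(s$n, 3L)
  expect_identical(c(s$median, s$mean, s$sd, s$total), c(2, 2, 1, 6))
  one <- summary_stats(5, "only")
  expect_true(is.na(one$sd))
  expect_identical(c(one$min_value, one$max_value), c(5, 5))
  expect_identical(one$min_ids, "only")
  tie <- summary_stats(c(2, 2, 9, 9), c("a", "b", "c", "d"))
  expect_identical(tie$median, 5.5)
  expect_identical(tie$min_ids, c("a", "b"))
  expect_identical(tie$max_ids, c("c", "d"))
  none <- summary_stats(numeric())
  expect_identical(none$n, 0L)
  expect_true(is.na(none$median) && is.na(none$total))
  expect_error(summary_stats(letters[1:3]), "numeric")
})

test_that("curated selection needs gene and transcript curation together", {
  genes <- rbind(
    toy_gene("G1", refseq_status = "REVIEWED"),   # only MODEL tx: drop
    toy_gene("G2", refseq_status = "VALIDATED"),  # VALIDATED NR + XR: keep
    toy_gene("G3", refseq_status = "PROVISIONAL"),# gene status: drop
    toy_gene("G4", refseq_status = "REVIEWED",
             in_current_annotation = FALSE))      # not current: drop
  tx <- rbind(toy_tx("XM_000001", "G1", "MODEL"),
              toy_tx("NR_000002", "G2", "VALIDATED"),
              toy_tx("XR_000003", "G2", "VALIDATED"),
              toy_tx("NM_000004", "G3", "REVIEWED"),
              toy_tx("NM_000005", "G4", "REVIEWED"))
  rows <- rbind(
    manual_rows("G1", "XM_000001", iv(c(100, 300), c(200, 400)),
                data.frame(start = c(150L, 300L), end = c(200L, 350L))),
    manual_rows("G2", "NR_000002", iv(c(1100, 1300), c(1200, 1400))),
    manual_rows("G2", "XR_000003", iv(c(1100, 1500), c(1200, 1600))),
    manual_rows("G3", "NM_000004", iv(2100, 2400),
                data.frame(start = 2150L, end = 2350L)),
    manual_rows("G4", "NM_000005", iv(3100, 3400),
                data.frame(start = 3150L, end = 3350L)))
  cur <- curated_subset(annotation_set(genes, tx, rows))
  expect_identical(cur$genes$gene_id, "G2")
  expect_identical(cur$transcripts$accession, "NR_000002")
  expect_identical(unique(cur$rows$accession), "NR_000002")
})

test_that("last-exon options and redundancy routing shape the summary", {
  g <- toy_gene("G1")
  tx <- rbind(toy_tx("NR_000001", "G1"), toy_tx("NR_000002", "G1"))
  # isoforms share exon (300,400) of length 101
  r <- rbind(
    manual_rows("G1", "NR_000001", iv(c(100, 300, 500), c(200, 400, 600))),
    manual_rows("G1", "NR_000002", iv(c(300, 700), c(400, 800))))
  a <- annotation_set(g, tx, r)
  one <- annotation_set(toy_gene("G1"), toy_tx("NR_000001", "G1"),
                        manual_rows("G1", "NR_000001",
                                    iv(c(100, 300, 500), c(200, 400, 600))))
  expect_identical(feature_summary(one, "exon_len", "per_row",
                                   exclude_last_exons = TRUE)$n, 2L)
  expect_identical(feature_summary(one, "exon_len", "per_row",
                                   last_exons_only = TRUE)$n, 1L)
  red <- feature_summary(a, "exon_len", "per_row")
  nonred <- feature_summary(a, "exon_len", "per_row",
                            redundancy = "non_redundant")
  expect_identical(red$total - nonred$total, 101L)  # one shared exon
  expect_error(feature_summary(a, "mature_len", "per_transcript",
                               redundancy = "non_redundant"),
               "non_redundant")
  expect_error(feature_summary(a, "intron_len", "per_row",
                               exclude_last_exons = TRUE),
               "last-exon options")
  expect_error(feature_summary(a, "exon_len", "per_row",
                               exclude_last_exons = TRUE,
                               last_exons_only = TRUE), "mutually exclusive")
})

test_that("chromosome breakdown groups types and tallies unplaced genes", {
  genes <- rbind(toy_gene("G1", chrom = "chrA"),
                 toy_gene("G2", chrom = "chrA"),
                 toy_gene("G3", chrom = "chrA"),
                 toy_gene("G4", chrom = "chrB", gene_type = "pseudo"),
                 toy_gene("G5", chrom = "chrA", gene_type = "snoRNA"),
                 toy_gene("G6", chrom = NA, gene_type = "ncRNA"))
  bd <- chromosome_breakdown(genes)
  expect_identical(bd$n[bd$chrom == "chrA" & bd$group == "protein_coding"],
                   3L)
  expect_identical(bd$n[bd$chrom == "chrB" & bd$group == "pseudo"], 1L)
  expect_identical(bd$n[bd$chrom == "chrA" & bd$group == "noncoding"], 1L)
  expect_identical(bd$chrom[bd$group == "noncoding" & bd$n == 1L],
                   c("chrA", "unplaced"))
  expect_identical(sum(bd$n), attr(bd, "total"))
  expect_identical(attr(bd, "total"), nrow(genes))
})

test_that("a gene covering the whole toy genome gives a 100% fraction", {
  g <- toy_gene("G1", chrom = "chrT")
  tx <- toy_tx("NM_000001", "G1")
  r <- manual_rows("G1", "NM_000001", iv(c(1, 501), c(400, 1000)),
                   data.frame(start = c(101L, 501L), end = c(400L, 900L)))
  a <- annotation_set(g, tx, r)
  asm <- genome_assembly(lengths = c(chrT = 1000L))
  fr <- genome_fraction_report(a, asm)
  pick <- function(m) fr$pct[fr$metric == m]
  expect_equal(pick("combined_gene_fraction"), 100)
  expect_equal(pick("pc_gene_fraction"), 100)
  expect_equal(pick("nc_gene_fraction"), 0)
  # per-base accounting: exons 400+500, coding 300+400 of a 1000 bp genome
  expect_equal(pick("exon_fraction_of_genome"), 90)
  expect_equal(pick("coding_fraction_of_exons"), 100 * 700 / 900)
  expect_equal(pick("coding_fraction_of_genome"), 70)
  expect_equal(pick("mrna_fraction_of_gene_dna"), 90)
  expect_equal(pick("intronless_transcript_fraction"), 0)
  expect_equal(pick("multi_isoform_gene_fraction"), 0)
})

test_that("fractions match a per-base bitmap on a no-overlap fixture", {
  fx <- make_fixture(fixture_spec(seed = 12, n_genes = 40, isoform_freq = 1,
                                  p_alt_boundary = 0))
  cur <- curated_subset(fx$annotation)
  fr <- genome_fraction_report(cur, fx$assembly)
  # bitmap oracle: mark covered bases per chromosome
  bit <- function(rows_sel, scol, ecol) {
    covered <- 0L
    for (ch in names(fx$assembly$lengths)) {
      v <- rep(FALSE, fx$assembly$lengths[[ch]])
      r <- rows_sel[rows_sel$chrom == ch & !is.na(rows_sel[[scol]]), ]
      for (i in seq_len(nrow(r))) v[r[[scol]][i]:r[[ecol]][i]] <- TRUE
      covered <- covered + sum(v)
    }
    covered
  }
  pc_genes <- cur$genes$gene_id[cur$genes$gene_type == "protein-coding"]
  nm_rows <- cur$rows[cur$rows$gene_id %in% pc_genes &
                        accession_prefix(cur$rows$accession) == "NM_", ]
  genome <- sum(as.numeric(fx$assembly$lengths))
  pick <- function(m) fr$pct[fr$metric == m]
  expect_equal(pick("exon_fraction_of_genome"),
               100 * bit(nm_rows, "exon_start", "exon_end") / genome)
  expect_equal(pick("coding_fraction_of_genome"),
               100 * bit(nm_rows, "cds_start", "cds_end") / genome)
})

test_that("QC flags catch artefactual minima without dropping records", {
  g <- toy_gene("G1", gene_type = "ncRNA")
  tx <- toy_tx("NR_000001", "G1")
  r <- manual_rows("G1", "NR_000001", iv(c(100, 230), c(200, 300)))
  q <- qc_flags(annotation_set(g, tx, r))  # intron 201..229 = 29 bp
  expect_identical(q$rule, "intron_lt_30")
  expect_identical(q$value, 29L)
  clean <- make_fixture(fixture_spec(seed = 13, n_genes = 15))
  expect_identical(nrow(qc_flags(clean$annotation)), 0L)
})

test_that("summaries recompute identically over any filtered subset", {
  fx <- make_fixture(fixture_spec(seed = 17, n_genes = 30))
  rows <- row_features(fx$annotation)
  set.seed(17)
  for (rep in 1:15) {
    lo <- sample(30:150, 1); hi <- lo + sample(50:500, 1)
    pref <- sample(c("NM_", "NR_", "X", "N"), 1)
    spec <- filter_spec(flt_range("exon_len", lo, hi),
                        flt_prefix("accession", pref))
    via_engine <- feature_summary(fx$annotation, "exon_len", "per_row",
                                  filter = spec)
    manual <- rows[rows$exon_len >= lo & rows$exon_len <= hi &
                     startsWith(rows$accession, pref), ]
    by_hand <- summary_stats(manual$exon_len, rid(manual))
    expect_identical(stats_as_list(via_engine, SUMMARY_FIELDS),
                     stats_as_list(by_hand, SUMMARY_FIELDS))
  }
})
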