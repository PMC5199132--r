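test_that("introns are the gaps between transcription-consecutive exons", {
  out <- infer_introns(iv(c(100, 300, 500), c(200, 400, 600)))
  expect_identical(out$start, c(201L, 401L))
  expect_identical(out$end, c(299L, 499L))
  expect_identical(nrow(infer_introns(iv(100, 200))), 0L)
  # minus strand, transcription order input; single intron of 299 bp
  out_m <- infer_introns(iv(c(500, 100), c(600, 200), strand = "-"))
  expect_identical(nrow(out_m), 1L)
  expect_identical(c(out_m$start, out_m$end), c(201L, 499L))
  expect_identical(interval_length(out_m), 299L)
  expect_error(infer_introns(iv(c(100, 201), c(200, 300)), "NM_X"),
               "abutting.*NM_X")
})

test_that("coding parts are exon/CDS intersections, stop codon included", {
  ex <- iv(c(100, 300), c(200, 400))
  p <- coding_exon_intervals(ex, iv(150, 350))
  expect_identical(p$start, c(150L, 300L))
  expect_identical(p$end, c(200L, 350L))
  # a single coding base in an exon is legal
  p1 <- coding_exon_intervals(ex, iv(200, 350))
  expect_identical(c(p1$start[1], p1$end[1]), c(200L, 200L))
  expect_identical(p1$end[1] - p1$start[1] + 1L, 1L)
  # CDS sticking out of every exon is a hard error
  expect_error(coding_exon_intervals(ex, iv(250, 260), "NM_X"),
               "outside exons.*NM_X")
  expect_identical(coding_exon_intervals(ex, NULL)$start,
                   c(NA_integer_, NA_integer_))
})

test_that("UTR/CDS lengths match the per-base labeling on both strands", {
  # plus strand: exons (100,200)+(300,400), cds (150,200)+(300,350)
  ex <- iv(c(100, 300), c(200, 400))
  parts <- data.frame(start = c(150L, 300L), end = c(200L, 350L))
  a <- annotation_set(toy_gene("G1"), toy_tx("NM_000001", "G1"),
                      manual_rows("G1", "NM_000001", ex, parts))
  tf <- transcript_features(a)
  expect_identical(c(tf$mature_len, tf$utr5_len, tf$cds_len, tf$utr3_len),
                   c(202L, 50L, 102L, 50L))
  o <- oracle_utr_cds(ex, parts)
  expect_identical(tf$utr5_len, o$utr5)

  # minus strand mirror: exons (300,400),(100,200) tx order, cds clipped
  exm <- iv(c(300, 100), c(400, 200), strand = "-")
  partsm <- data.frame(start = c(300L, 150L), end = c(350L, 200L))
  am <- annotation_set(toy_gene("G2", strand = "-"),
                       toy_tx("NM_000002", "G2"),
                       manual_rows("G2", "NM_000002", exm, partsm))
  tfm <- transcript_features(am)
  expect_identical(c(tfm$mature_len, tfm$utr5_len, tfm$cds_len,
                     tfm$utr3_len), c(202L, 50L, 102L, 50L))

  # 0 bp UTRs are legal when the CDS reaches the transcript ends
  full <- annotation_set(toy_gene("G3"), toy_tx("NM_000003", "G3"),
                         manual_rows("G3", "NM_000003", iv(10, 42),
                                     data.frame(start = 10L, end = 42L)))
  tfull <- transcript_features(full)
  expect_identical(c(tfull$utr5_len, tfull$utr3_len), c(0L, 0L))
})

test_that("features agree with the brute-force per-base labeler", {
  set.seed(42)
  for (rep in 1:250) {
    cs <- random_transcript_case()
    acc <- if (cs$coding) "NM_900001" else "NR_900001"
    a <- annotation_set(toy_gene("G1", strand = cs$exons$strand[1]),
                        toy_tx(acc, "G1"),
                        manual_rows("G1", acc, cs$exons, cs$parts))
    tf <- transcript_features(a)
    o <- oracle_utr_cds(cs$exons, cs$parts)
    expect_identical(tf$mature_len, o$mature)
    expect_identical(tf$utr5_len, o$utr5)
    expect_identical(tf$cds_len, o$cds)
    expect_identical(tf$utr3_len, o$utr3)
    # and with the constructive expectation from the CDS window
    expect_identical(tf$utr5_len, cs$expected$utr5)
    expect_identical(tf$cds_len, cs$expected$cds)
    expect_identical(tf$utr3_len, cs$expected$utr3)
    # conservation (coding transcripts) and count identities
    if (cs$coding)
      expect_identical(tf$utr5_len + tf$cds_len + tf$utr3_len,
                       tf$mature_len)
    expect_identical(tf$n_introns, tf$n_exons - 1L)
    expect_identical(tf$is_monoexonic, tf$n_exons == 1L)
  }
})

test_that("gene length is the exon-union envelope with a span fallback", {
  g <- toy_gene("G1")
  tx <- rbind(toy_tx("NM_000001", "G1"), toy_tx("NM_000002", "G1"))
  r <- rbind(
    manual_rows("G1", "NM_000001", iv(c(100, 300), c(200, 400)),
                data.frame(start = c(150L, 300L), end = c(200L, 350L))),
    manual_rows("G1", "NM_000002", iv(c(150, 550), c(250, 600)),
                data.frame(start = c(160L, NA), end = c(250L, NA))))
  gf <- gene_features(annotation_set(g, tx, r))
  expect_identical(gf$gene_len, 501L)
  expect_identical(gf$n_transcripts, 2L)
  # transcript-less gene: annotated span is the fallback
  trna <- annotation_set(toy_gene("T1", gene_type = "tRNA",
                                  span_start = 10, span_end = 82))
  expect_identical(gene_features(trna)$gene_len, 73L)
  expect_identical(gene_features(trna)$n_transcripts, 0L)
})

test_that("the most-exon isoform is reported with a deterministic tie-break", {
  g <- toy_gene("G1")
  tx <- rbind(toy_tx("NR_000005", "G1"), toy_tx("NR_000001", "G1"),
              toy_tx("NR_000003", "G1"))
  r <- rbind(
    manual_rows("G1", "NR_000005", iv(c(100, 300, 500), c(200, 400, 600))),
    manual_rows("G1", "NR_000001",
                iv(c(100, 300, 500, 700, 900),
                   c(200, 400, 600, 800, 1000))),
    manual_rows("G1", "NR_000003",
                iv(c(100, 300, 500, 700, 900),
                   c(200, 400, 600, 800, 1000))))
  gf <- gene_features(annotation_set(g, tx, r))
  expect_identical(gf$max_exons, 5L)  # 5 beats 3
  # tie between NR_000001 and NR_000003 resolved to smallest accession;
  # both have 0 coding exons so the value is identical by construction,
  # check via a coding/non-coding asymmetry instead
  r2 <- r
  r2$cds_start[r2$accession == "NR_000001"] <- NA_integer_
  gf2 <- gene_features(annotation_set(g, tx, r))
  expect_identical(gf2$max_coding_exons, 0L)
})

test_that("exon+intron lengths partition the gene span of one isoform", {
  set.seed(7)
  for (rep in 1:20) {
    cs <- random_transcript_case(max_exons = 10L)
    introns <- infer_introns(cs$exons)
    span <- max(cs$exons$end) - min(cs$exons$start) + 1L
    expect_identical(sum(interval_length(cs$exons)) +
                       sum(if (nrow(introns)) interval_length(introns)
                           else 0L), span)
  }
})

test_that("exon position classes follow transcription order", {
  expect_identical(exon_position_class(1L, 1L), "single")
  expect_identical(exon_position_class(4L, 4L), "last")
  expect_identical(exon_position_class(4L, 1L), "first")
  expect_identical(exon_position_class(4L, 3L), "internal")
  # minus strand: last exon in transcription order has the smallest
  # genomic start, which is simply index n
  expect_identical(exon_position_class(c(3L, 3L, 3L), 1:3),
                   c("first", "internal", "last"))
  expect_error(exon_position_class(3L, 4L), "out of range")
})
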