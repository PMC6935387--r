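test_that("gc_content counts G+C over unambiguous bases only", {
  expect_equal(gc_content("GGCC"), 1.0)
  expect_equal(gc_content("ATAT"), 0.0)
  expect_equal(gc_content("ACGTN"), 0.5)
  expect_error(gc_content(""))
  expect_error(gc_content("NNN"))
})

test_that("retained-intron consequence classes follow the reading frame", {
  # phase 0, intron starting with an immediate TAA
  codons <- "ATGGCTGCTCATCAT"                     # 5 stop-free codons
  intron0 <- paste0("TAAGCC", strrep("C", 24))    # 30 nt, in-frame TAA
  make <- function(intron) {
    chrom <- paste0(codons, intron, "GCTGCTGGT")
    g <- tiny_genome(list(c1 = chrom))
    l1 <- nchar(codons); L <- nchar(intron)
    tx <- tiny_tx(list(c(0L, l1), c(l1 + L, nchar(chrom))), chrom = "c1",
                  cds = list(c(0L, l1), c(l1 + L, nchar(chrom))))
    list(g = g, tx = tx, iv = c(l1, l1 + L))
  }
  x <- make(intron0)
  expect_equal(classify_ri_consequence(x$tx, x$iv, x$g), "in_frame_stop")

  # frame-preserving intron without stops
  x <- make(strrep("CAG", 11))                    # 33 nt, no stop
  expect_equal(classify_ri_consequence(x$tx, x$iv, x$g), "no_ptc")

  # frame-shifting intron (31 nt, shift 1), no stop inside; the downstream
  # exon carries a TAA in the shifted frame ("CC" completes the junction
  # codon, then TAA)
  chrom <- paste0(codons, strrep("CAG", 10), "C", "CCTAAGGG")
  g <- tiny_genome(list(c1 = chrom))
  l1 <- nchar(codons); L <- 31L
  tx <- tiny_tx(list(c(0L, l1), c(l1 + L, nchar(chrom))), chrom = "c1",
                cds = list(c(0L, l1), c(l1 + L, nchar(chrom))))
  expect_equal(classify_ri_consequence(tx, c(l1, l1 + L), g),
               "frameshift_ptc_downstream")

  # no CDS -> frame unavailable; foreign interval -> error
  tx_nocds <- tiny_tx(list(c(0L, l1), c(l1 + 31L, nchar(chrom))), chrom = "c1")
  expect_equal(classify_ri_consequence(tx_nocds, c(l1, l1 + 31L), g),
               "frame_unavailable")
  expect_error(classify_ri_consequence(tx, c(1L, 5L), g), "not an intron")
})

test_that("consequence classification agrees with a translate-and-scan oracle", {
  set.seed(202)
  n_agree <- 0L
  for (i in 1:150) {
    rc <- random_ri_construct()
    got <- classify_ri_consequence(rc$tx, rc$intron, rc$genome)
    want <- oracle_ri_consequence(rc$up_cds, rc$intron_seq, rc$down_cds)
    if (identical(got, want)) n_agree <- n_agree + 1L
  }
  expect_equal(n_agree, 150L)
})

test_that("feature extraction recovers planted ground truth exactly", {
  fix <- sp_fixture()
  me <- fix$ds$manifest_events
  rf <- read.delim(file.path(fix$outdir, "ri_features.tsv"))
  m <- merge(rf, me, by.x = "item_id", by.y = "event_id")
  expect_equal(nrow(m), sum(me$kind == "RI"))
  expect_equal(m$focal_length.x, m$focal_length.y)
  expect_equal(m$bp_offset.x, m$bp_offset.y)
  expect_equal(m$ri_consequence, m$consequence)
  expect_equal(m$group.x, m$group.y)
  expect_equal(m$intron_start, m$focal_start)
  expect_equal(m$intron_end, m$focal_end)
  # trained-model scores of the manifest's planted donor windows match the
  # pipeline's genome-extracted scores
  models <- list(donor = train_splice_model(
    collect_training_sites(fix$annotation, fix$genome, "donor"), "donor",
    background = genome_background(fix$genome)))
  expect_equal(m$donor_score, score_site(models$donor, m$donor_window))

  sf <- read.delim(file.path(fix$outdir, "se_features.tsv"))
  ms <- merge(sf, me, by.x = "item_id", by.y = "event_id")
  expect_equal(nrow(ms), sum(me$kind == "SE"))
  expect_equal(ms$focal_length.x, ms$focal_length.y)
  expect_equal(ms$bp_offset_upstream, ms$bp_offset)
  expect_equal(ms$bp_offset_downstream.x, ms$bp_offset_downstream.y)
  expect_equal(ms$exon_start, ms$focal_start)
})

test_that("SE anatomy wires the four splice-site scores to the right junctions", {
  fix <- sp_fixture()
  sf <- read.delim(file.path(fix$outdir, "se_features.tsv"))
  ev <- classify_direction(filter_events(
    parse_rmats_table(fix$ds$paths$SE, "SE")), TRUE)
  models <- list(
    donor = train_splice_model(
      collect_training_sites(fix$annotation, fix$genome, "donor"), "donor",
      background = genome_background(fix$genome)),
    acceptor = train_splice_model(
      collect_training_sites(fix$annotation, fix$genome, "acceptor"), "acceptor",
      background = genome_background(fix$genome)))
  i <- 1L
  row <- sf[sf$item_id == ev$event_id[i], ]
  e <- ev[i, ]
  if (e$strand == "+") {
    up_in <- c(e$upstream_ee, e$exon_start); down_in <- c(e$exon_end, e$downstream_es)
  } else {
    up_in <- c(e$exon_end, e$upstream_es); down_in <- c(e$downstream_ee, e$exon_start)
  }
  dw <- site_window(fix$genome, e$chrom, down_in[1], down_in[2], e$strand, "donor")
  aw <- site_window(fix$genome, e$chrom, up_in[1], up_in[2], e$strand, "acceptor")
  expect_equal(row$donor_score, score_site(models$donor, dw))
  expect_equal(row$acceptor_score, score_site(models$acceptor, aw))
  expect_equal(row$upstream_intron_len, up_in[2] - up_in[1])
  expect_equal(row$downstream_intron_len, down_in[2] - down_in[1])
})

test_that("length-threshold fractions are monotone in the threshold", {
  fix <- sp_fixture()
  rf <- read.delim(file.path(fix$outdir, "ri_features.tsv"))
  v <- rf$focal_length
  fr <- vapply(c(100, 500, 1000, 5000, 1e6), function(t)
    fraction_below(v, t), numeric(1))
  expect_true(all(diff(fr) >= 0))
  expect_equal(fr[length(fr)], 1)
})
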