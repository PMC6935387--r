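test_that("training yields normalized probabilities and honours pseudocounts", {
  m <- train_splice_model(rep("CAGGTAAGT", 10), "donor", pseudocount = 0)
  expect_true(all(abs(rowSums(m$probs) - 1) < 1e-9))
  expect_equal(unname(m$probs[1, "C"]), 1)
  expect_equal(unname(m$probs[4, "G"]), 1)

  m2 <- train_splice_model(rep("CAGGTAAGT", 10), "donor", pseudocount = 0.5)
  expect_true(all(abs(rowSums(m2$probs) - 1) < 1e-9))
  expect_equal(unname(m2$probs[1, "C"]), 10.5 / 12)

  expect_error(train_splice_model(character(0), "donor"), "no training windows")
  expect_error(train_splice_model(c("CAGGTAAGT", "CAGGT"), "donor"), "9 nt")
  expect_error(train_splice_model("CAGGTAAGN", "donor"), "A/C/G/T")
})

test_that("scores are log2 odds: uniform model scores 0, indicator model 18 bits", {
  uni <- train_splice_model("CAGGTAAGT", "donor")
  uni$probs[] <- 0.25
  expect_equal(score_site(uni, "ACGTACGTA"), 0)

  ind <- train_splice_model(rep("CAGGTAAGT", 5), "donor", pseudocount = 0)
  expect_equal(score_site(ind, "CAGGTAAGT"), 9 * log2(4))
  expect_error(score_site(ind, "CAGGTAAGN"))
  expect_error(score_site(ind, "CAGG"))
})

test_that("score_site matches an independently coded log-odds sum", {
  set.seed(7)
  train <- sample_windows(generator_donor_pwm(), 400)
  m <- train_splice_model(train, "donor", background = c(A = .3, C = .2,
                                                         G = .2, T = .3))
  windows <- sample_windows(generator_donor_pwm(), 100)
  # independent oracle: naive per-position loop
  oracle <- vapply(windows, function(w) {
    b <- strsplit(w, "")[[1]]
    s <- 0
    for (p in seq_along(b))
      s <- s + log2(m$probs[p, b[p]] / m$background[b[p]])
    s
  }, numeric(1), USE.NAMES = FALSE)
  expect_lt(max(abs(score_site(m, windows) - oracle)), 1e-9)
})

test_that("score is strictly increasing in the matched base probability", {
  m <- train_splice_model(sample_windows(generator_donor_pwm(), 100), "donor")
  w <- "CAGGTAAGT"
  s0 <- score_site(m, w)
  m2 <- m
  m2$probs[1, "C"] <- m2$probs[1, "C"] * 1.5
  expect_gt(score_site(m2, w), s0)
})

test_that("training window collection is strand-correct and filters non-canonical introns", {
  # one plus gene and its hand-mirrored minus twin must give identical windows
  exon1 <- "ATGGCTGCTCAG"; intron <- paste0("GTAAGT", strrep("C", 30), "TACTAAC",
                                            strrep("CT", 8), "CAG")
  exon2 <- "GCTTGGTCTTGA"
  plus_chrom <- paste0(exon1, intron, exon2)
  l1 <- nchar(exon1); li <- nchar(intron); lt <- nchar(plus_chrom)
  minus_chrom <- revcomp(plus_chrom)
  g <- tiny_genome(list(p = plus_chrom, m = minus_chrom))
  tx_p <- tiny_tx(list(c(0L, l1), c(l1 + li, lt)), chrom = "p")
  tx_m <- tiny_tx(list(c(lt - l1, lt), c(0L, lt - l1 - li)), strand = "-",
                  chrom = "m", gene_id = "G2", transcript_id = "T2")
  ann <- structure(list(genes = list(
    G1 = tiny_gene(list(T1 = tx_p)),
    G2 = tiny_gene(list(T2 = tx_m), gene_id = "G2", chrom = "m", strand = "-")
  )), class = "sp_annotation")
  dw <- collect_training_sites(ann, g, "donor")
  aw <- collect_training_sites(ann, g, "acceptor")
  expect_length(dw, 2L)
  expect_equal(dw[1], dw[2])
  expect_equal(dw[1], "CAGGTAAGT")
  expect_equal(aw[1], aw[2])
  expect_equal(substr(aw[1], 18, 23), "CAGGCT")

  # GC..AG intron is skipped and counted
  gc_intron <- sub("^GT", "GC", intron)
  g2 <- tiny_genome(list(p = paste0(exon1, gc_intron, exon2)))
  ann2 <- structure(list(genes = list(G1 = tiny_gene(list(T1 = tx_p)))),
                    class = "sp_annotation")
  dw2 <- collect_training_sites(ann2, g2, "donor")
  expect_length(dw2, 0L)
  expect_equal(attr(dw2, "n_skipped_noncanonical"), 1L)
})

test_that("external score tables are lookup scorers with strict errors", {
  f <- tempfile()
  writeLines(c("CAGGTAAGT\t10.86", "AAGGTAAGT\t9.1"), f)
  sc <- load_external_score_tables(f)
  expect_equal(score_site(sc, "CAGGTAAGT"), 10.86)
  expect_equal(score_site(sc, c("AAGGTAAGT", "CAGGTAAGT")), c(9.1, 10.86))
  expect_error(score_site(sc, "TTTTTTTTT"), "absent")
  writeLines(character(0), f)
  expect_error(load_external_score_tables(f), "empty")
})

test_that("branch point search finds a planted consensus and applies the tie-break", {
  # unique planted TACTAAC whose branch A sits 30 nt from the 3' end
  intron <- strrep("C", 80)
  plant_at <- 80 - 30 - 4  # 7-mer start so that the A (pos 5) has offset 30
  substr(intron, plant_at, plant_at + 6) <- "TACTAAC"
  bp <- find_branch_point(intron)
  expect_equal(bp$bp_offset, 30L)
  expect_equal(bp$sequence_context, "TACTAAC")

  expect_null(find_branch_point(strrep("C", 80)))         # no A at all
  expect_null(find_branch_point(strrep("C", 10)))         # too short

  # two identical candidates: the one closest to the 3'SS wins
  intron2 <- strrep("C", 100)
  for (off in c(40, 25)) {
    s <- 100 - off - 4
    substr(intron2, s, s + 6) <- "TACTAAC"
  }
  expect_equal(find_branch_point(intron2)$bp_offset, 25L)
})

test_that("branch point offsets always fall inside the search window", {
  set.seed(31)
  for (i in 1:40) {
    L <- sample(60:800, 1)
    seqs <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
    bp <- find_branch_point(seqs, search_min = 15, search_max = 500)
    if (!is.null(bp)) {
      expect_gte(bp$bp_offset, 15)
      expect_lte(bp$bp_offset, 500)
    }
  }
})

test_that("models trained on a genome and its mirror are identical", {
  dir <- file.path(tempdir(), "mirror_model_ds")
  cfg <- synthetic_config(seed = 77, n_genes = 120, n_ri_events = 8,
                          n_se_events = 8, genes_per_chrom = 40)
  ds <- generate_dataset(cfg, dir)
  mdir <- file.path(tempdir(), "mirror_model_ds_m")
  mirror_dataset(dir, mdir)
  g1 <- load_genome(ds$paths$genome); a1 <- load_annotation(ds$paths$gtf)
  g2 <- load_genome(file.path(mdir, "genome.fa"))
  a2 <- load_annotation(file.path(mdir, "annotation.gtf"))
  m1 <- train_splice_model(collect_training_sites(a1, g1, "donor"), "donor",
                           background = genome_background(g1))
  m2 <- train_splice_model(collect_training_sites(a2, g2, "donor"), "donor",
                           background = genome_background(g2))
  expect_equal(m1$counts, m2$counts)
  expect_equal(m1$background, m2$background)
  expect_equal(m1$probs, m2$probs)
})
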