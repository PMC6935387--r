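test_that("FASTA loading normalizes case, maps ambiguity codes and validates names", {
  fa <- tempfile(fileext = ".fa")
  writeLines(c(">chr1 description text", "AACGTTacgt", ">chr2", "NNRYAC"), fa)
  expect_warning(g <- load_genome(fa), "ambiguity")
  expect_equal(unname(genome_lengths(g)), c(10L, 6L))
  expect_equal(names(g), c("chr1", "chr2"))
  expect_equal(as.character(g[["chr1"]]), "AACGTTACGT")
  expect_equal(as.character(g[["chr2"]]), "NNNNAC")

  writeLines(c(">chr1", "ACGT", ">chr1", "ACGT"), fa)
  expect_error(load_genome(fa), "duplicate")
  writeLines(character(0), fa)
  expect_error(load_genome(fa))
})

test_that("get_sequence is strand-aware and bounds-checked", {
  g <- tiny_genome(list(chr1 = "AACGTT"))
  expect_equal(get_sequence(g, "chr1", 1, 4, "+"), "ACG")
  expect_equal(get_sequence(g, "chr1", 1, 4, "-"), "CGT")
  expect_error(get_sequence(g, "chr1", 4, 10, "+"), "out of bounds")
  expect_error(get_sequence(g, "chrX", 0, 1, "+"), "unknown chromosome")
})

test_that("minus-strand extraction equals reverse complement of plus strand", {
  set.seed(101)
  g <- tiny_genome(list(c1 = paste(sample(c("A", "C", "G", "T"), 300,
                                          replace = TRUE), collapse = "")))
  for (i in 1:25) {
    s <- sample(0:250, 1); e <- s + sample(1:49, 1)
    expect_equal(get_sequence(g, "c1", s, e, "-"),
                 revcomp(get_sequence(g, "c1", s, e, "+")))
  }
})

test_that("GTF coordinates convert to 0-based half-open and introns derive as gaps", {
  gtf <- tempfile(fileext = ".gtf")
  writeLines(c(
    paste0('c1\tsrc\texon\t11\t20\t.\t+\t.\tgene_id "G1"; transcript_id "T1"; ',
           'gene_type "protein_coding"; transcript_type "protein_coding"; ',
           'transcript_support_level "1";'),
    paste0('c1\tsrc\texon\t31\t40\t.\t+\t.\tgene_id "G1"; transcript_id "T1"; ',
           'gene_type "protein_coding"; transcript_type "protein_coding"; ',
           'transcript_support_level "1";')), gtf)
  ann <- load_annotation(gtf)
  tx <- ann$genes$G1$transcripts$T1
  expect_equal(unname(tx$exons[, "start"]), c(10, 30))
  expect_equal(unname(tx$exons[, "end"]), c(20, 40))
  introns <- tx_introns(tx)
  expect_equal(unname(introns[1, ]), c(20, 30))
  expect_equal(tx_spliced_length(tx), 20)
})

test_that("annotation round-trips through GTF export and reload", {
  fix <- sp_fixture()
  ann <- fix$annotation
  # re-emit exon lines from the loaded models and reload them
  gtf2 <- tempfile(fileext = ".gtf")
  lines <- unlist(lapply(ann$genes[1:25], function(g) {
    unlist(lapply(g$transcripts, function(tx) {
      sprintf(paste0('%s\tx\texon\t%d\t%d\t.\t%s\t.\tgene_id "%s"; ',
                     'transcript_id "%s"; transcript_type "%s"; ',
                     'transcript_support_level "%s";'),
              tx$chrom, tx$exons[, "start"] + 1L, tx$exons[, "end"],
              tx$strand, g$gene_id, tx$transcript_id, tx$biotype, tx$tsl)
    }))
  }))
  writeLines(lines, gtf2)
  ann2 <- load_annotation(gtf2)
  for (gid in names(ann2$genes)) {
    t1 <- ann$genes[[gid]]$transcripts[[1]]
    t2 <- ann2$genes[[gid]]$transcripts[[1]]
    expect_equal(unname(t2$exons), unname(t1$exons))
    expect_equal(t2$strand, t1$strand)
    expect_equal(t2$tsl, t1$tsl)
  }
})

test_that("reference transcript selection follows length, then TSL, then id", {
  t_long <- tiny_tx(list(c(0L, 1500L)), transcript_id = "T_long", tsl = 2L)
  t_short <- tiny_tx(list(c(2000L, 2900L)), transcript_id = "T_short", tsl = 1L)
  g <- tiny_gene(list(T_long = t_long, T_short = t_short))
  expect_equal(select_reference_transcript(g)$transcript_id, "T_long")

  # equal length: lowest TSL wins
  a <- tiny_tx(list(c(0L, 900L)), transcript_id = "Ta", tsl = 3L)
  b <- tiny_tx(list(c(0L, 900L)), transcript_id = "Tb", tsl = 1L)
  expect_equal(select_reference_transcript(tiny_gene(list(a, b)))$transcript_id, "Tb")

  # equal length and TSL: smallest id
  b2 <- tiny_tx(list(c(0L, 900L)), transcript_id = "Aa", tsl = 3L)
  expect_equal(select_reference_transcript(tiny_gene(list(a, b2)))$transcript_id, "Aa")

  # non-coding or TSL-less transcripts never qualify
  lnc <- tiny_tx(list(c(0L, 5000L)), transcript_id = "L1", biotype = "lncRNA")
  no_tsl <- tiny_tx(list(c(0L, 5000L)), transcript_id = "N1", tsl = NA_integer_)
  expect_null(select_reference_transcript(tiny_gene(list(lnc))))
  expect_null(select_reference_transcript(tiny_gene(list(no_tsl))))
  expect_equal(select_reference_transcript(
    tiny_gene(list(lnc, no_tsl, a)))$transcript_id, "Ta")
})

test_that("exon sequence length equals summed exon interval length", {
  fix <- sp_fixture()
  for (gid in names(fix$annotation$genes)[1:10]) {
    tx <- fix$annotation$genes[[gid]]$transcripts[[1]]
    seqs <- vapply(seq_len(nrow(tx$exons)), function(i)
      get_sequence(fix$genome, tx$chrom, tx$exons[i, 1], tx$exons[i, 2],
                   tx$strand), character(1))
    expect_equal(sum(nchar(seqs)), tx_spliced_length(tx))
  }
})
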