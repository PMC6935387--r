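# A transcript with n equal exons of 50 nt separated by 100 nt introns.
ladder_tx <- function(n_exons, gene_id = "G1") {
  exons <- lapply(seq_len(n_exons) - 1L, function(i)
    c(i * 150L, i * 150L + 50L))
  tiny_tx(exons, gene_id = gene_id)
}

ri_event_row <- function(gene = "G1", up = c(0L, 50L), dn = c(150L, 200L)) {
  data.frame(event_id = "RI_1", kind = "RI", gene_id = gene, chrom = "chr1",
             strand = "+", upstream_es = up[1], upstream_ee = up[2],
             downstream_es = dn[1], downstream_ee = dn[2],
             intron_start = up[2], intron_end = dn[1],
             ri_exon_start = up[1], ri_exon_end = dn[2],
             p_value = 0.01, fdr = 0.01, inc_level_diff = -0.2,
             stringsAsFactors = FALSE)
}

test_that("event footprints span the whole construct region", {
  ev <- ri_event_row(up = c(0L, 50L), dn = c(200L, 260L))
  ev$intron_start <- 50L; ev$intron_end <- 200L
  fp <- event_footprints(ev)
  expect_equal(unname(fp[1, ]), c(0, 260))
  expect_equal(nrow(event_footprints(rbind(ev, ev))), 2L)
  expect_equal(nrow(event_footprints(ev[0, ])), 0L)
})

test_that("internal candidate enumeration excludes footprint overlaps", {
  # 3 exons, event in intron 1: the only other E-I-E shares exon 2 -> none
  tx3 <- ladder_tx(3L)
  fp <- event_footprints(ri_event_row())
  expect_length(enumerate_internal_candidates(tx3, fp, "EIE"), 0L)

  # 4 exons, same event: exactly one clean window, E3-I3-E4
  tx4 <- ladder_tx(4L)
  cands <- enumerate_internal_candidates(tx4, fp, "EIE")
  expect_length(cands, 1L)
  expect_equal(cands[[1]]$first_exon, 3L)
  expect_equal(cands[[1]]$segments$role, c("exon", "intron", "exon"))
  expect_equal(cands[[1]]$segments$start, c(300L, 350L, 450L))
  expect_equal(cands[[1]]$segments$end, c(350L, 450L, 500L))

  # SE event on exon 2 of a 6-exon transcript: one E-I-E-I-E window (E4..E6)
  tx6 <- ladder_tx(6L)
  se_fp <- cbind(start = 0L, end = 350L)  # E1..E3 span
  c5 <- enumerate_internal_candidates(tx6, se_fp, "EIEIE")
  expect_length(c5, 1L)
  expect_equal(c5[[1]]$first_exon, 4L)
  # same event on a 5-exon transcript: impossible
  expect_length(enumerate_internal_candidates(ladder_tx(5L), se_fp, "EIEIE"), 0L)
})

test_that("construct segments alternate and abut along the transcript", {
  fix <- sp_fixture()
  tab <- read.delim(file.path(fix$outdir, "controls.tsv"))
  ccs <- table_to_constructs(tab)
  for (cc in ccs[seq(1, length(ccs), length.out = min(50, length(ccs)))]) {
    seg <- cc$segments
    expect_equal(seg$role, if (cc$shape == "EIE")
      c("exon", "intron", "exon") else
        c("exon", "intron", "exon", "intron", "exon"))
    ord <- if (cc$strand == "+") seq_len(nrow(seg)) else rev(seq_len(nrow(seg)))
    g <- seg[ord, ]
    expect_true(all(g$start[-1] == g$end[-nrow(g)]))
  }
})

test_that("sample_one is uniform, forced and empty-safe", {
  tx <- ladder_tx(7L)
  cands <- enumerate_internal_candidates(tx, cbind(start = integer(0),
                                                   end = integer(0)), "EIE")
  expect_length(cands, 6L)
  expect_null(sample_one(list()))
  expect_identical(sample_one(cands[1]), cands[[1]])

  five <- cands[1:5]
  set.seed(99)
  picks <- vapply(1:10000, function(i) sample_one(five)$first_exon, integer(1))
  freqs <- tabulate(picks, 5) / 10000
  expect_true(all(abs(freqs - 0.2) <= 0.02))

  set.seed(123); a <- sample_one(five)
  set.seed(123); b <- sample_one(five)
  expect_identical(a, b)
})

test_that("external gene selection applies every exclusion rule", {
  fix <- sp_fixture()
  mg <- fix$ds$manifest_genes
  expr <- load_expression_table(fix$ds$paths$expression)
  fe <- read.delim(file.path(fix$outdir, "filtered_events.tsv"))
  pool <- select_external_genes(expr, fix$annotation, unique(fe$gene_id),
                                "EIEIE", n = 60L)
  expect_length(pool, 60L)
  expect_length(intersect(pool, unique(fe$gene_id)), 0L)
  expect_length(intersect(pool, mg$gene_id[mg$chrom == "chrM"]), 0L)
  expect_length(intersect(pool, mg$gene_id[mg$role %in% c("lnc", "no_tsl")]), 0L)
  # mitochondrial decoys are the most expressed genes, so the exclusion bites
  expect_true(all(mg$gene_id[mg$chrom == "chrM"] %in%
                    expr$gene_id[order(-expr$expression)][1:5]))
  # ranked by expression among the kept genes
  expect_true(all(diff(expr$expression[match(pool, expr$gene_id)]) <= 0))

  # a 2-exon gene qualifies for EIE but not EIEIE
  two_exon <- tiny_gene(list(T1 = ladder_tx(2L)), gene_id = "G2EX")
  ann2 <- structure(list(genes = list(G2EX = two_exon)), class = "sp_annotation")
  e2 <- data.frame(gene_id = "G2EX", expression = 5)
  expect_length(suppressWarnings(
    select_external_genes(e2, ann2, character(0), "EIE", 10L)), 1L)
  expect_length(suppressWarnings(
    select_external_genes(e2, ann2, character(0), "EIEIE", 10L)), 0L)
})

test_that("external control construction is deterministic under a fixed seed", {
  fix <- sp_fixture()
  expr <- load_expression_table(fix$ds$paths$expression)
  pool <- select_external_genes(expr, fix$annotation, character(0), "EIE", 20L)
  set.seed(5); a <- build_external_controls(pool, fix$annotation, "EIE")
  set.seed(5); b <- build_external_controls(pool, fix$annotation, "EIE")
  expect_identical(constructs_to_table(a), constructs_to_table(b))
  expect_equal(constructs_to_table(a),
               constructs_to_table(table_to_constructs(constructs_to_table(a))))
})

test_that("internal controls never overlap their gene's event footprints", {
  fix <- sp_fixture()
  tab <- read.delim(file.path(fix$outdir, "controls.tsv"))
  internal <- table_to_constructs(tab[tab$origin == "internal", ])
  fe <- read.delim(file.path(fix$outdir, "filtered_events.tsv"))
  # reconstruct footprints from the raw tables
  kinds <- c("SE", "RI", "A5SS", "A3SS", "MXE")
  allev <- do.call(rbind, lapply(kinds, function(k) {
    ev <- filter_events(parse_rmats_table(fix$ds$paths[[k]], k))
    fp <- event_footprints(ev)
    data.frame(gene_id = ev$gene_id, start = fp[, "start"], end = fp[, "end"],
               stringsAsFactors = FALSE)
  }))
  for (cc in internal) {
    fps <- allev[allev$gene_id == cc$gene_id, , drop = FALSE]
    expect_gt(nrow(fps), 0)
    s <- cc$span[["start"]]; e <- cc$span[["end"]]
    expect_false(any(s < fps$end & fps$start < e))
  }
})
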