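# Shared fixtures, built in code at test time and memoized per session.

.fixture_cache <- new.env(parent = emptyenv())

# Mid-sized synthetic dataset plus a completed pipeline run.
sp_fixture <- function() {
  if (!is.null(.fixture_cache$fix)) return(.fixture_cache$fix)
  dir <- file.path(tempdir(), "spfix")
  cfg <- synthetic_config(seed = 42, n_genes = 220, n_ri_events = 40,
                          n_se_events = 40, genes_per_chrom = 44)
  ds <- generate_dataset(cfg, dir)
  outdir <- file.path(tempdir(), "spfix_out")
  rc <- run_config_for_dataset(dir, outdir, seed = 7,
                               external_pool_size = 80, run_motifs = FALSE)
  rep <- suppressWarnings(run_pipeline(rc))
  .fixture_cache$fix <- list(ds = ds, config = rc, report = rep,
                             outdir = outdir,
                             annotation = load_annotation(ds$paths$gtf),
                             genome = load_genome(ds$paths$genome))
  .fixture_cache$fix
}

# Write a small FASTA and return a loaded genome.
tiny_genome <- function(records) {
  fa <- tempfile(fileext = ".fa")
  writeLines(unlist(lapply(names(records), function(n)
    c(paste0(">", n), records[[n]]))), fa)
  load_genome(fa)
}

# Hand-built transcript model (0-based half-open intervals).
tiny_tx <- function(exons, strand = "+", chrom = "chr1", cds = NULL,
                    gene_id = "G1", transcript_id = "T1",
                    biotype = "protein_coding", tsl = 1L) {
  ex <- do.call(rbind, exons)
  colnames(ex) <- c("start", "end")
  ex <- ex[order(ex[, "start"]), , drop = FALSE]
  cd <- NULL
  if (!is.null(cds)) {
    cd <- do.call(rbind, lapply(cds, function(x) c(x, 0L)))
    colnames(cd) <- c("start", "end", "phase")
    cd <- cd[order(cd[, "start"]), , drop = FALSE]
  }
  list(gene_id = gene_id, transcript_id = transcript_id, chrom = chrom,
       strand = strand, biotype = biotype, tsl = tsl, exons = ex, cds = cd)
}

tiny_gene <- function(transcripts, gene_id = "G1", chrom = "chr1",
                      strand = "+", is_mito = FALSE) {
  list(gene_id = gene_id, gene_name = gene_id, chrom = chrom, strand = strand,
       biotype = "protein_coding", is_mitochondrial = is_mito,
       transcripts = transcripts)
}

# Random E-I-E coding construct on its own little chromosome, for the
# intron-retention consequence oracle. Exonic CDS is stop-free in frame 0;
# the intron is unconstrained random sequence. Returns the transcript,
# genome, and intron interval.
random_ri_construct <- function(strand = sample(c("+", "-"), 1)) {
  codon_pool <- setdiff(apply(expand.grid(B1 = c("A", "C", "G", "T"),
                                          B2 = c("A", "C", "G", "T"),
                                          B3 = c("A", "C", "G", "T")),
                              1, paste, collapse = ""),
                        c("TAA", "TAG", "TGA"))
  # one stop-free ORF split at a random point so the intron phase is 0/1/2
  n_cod <- sample(10:24, 1)
  orf <- paste(sample(codon_pool, n_cod, replace = TRUE), collapse = "")
  cut <- sample(seq(12L, nchar(orf) - 12L), 1)
  up <- substr(orf, 1, cut)
  dn <- substr(orf, cut + 1L, nchar(orf))
  L <- sample(20:90, 1)
  intron <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
                  collapse = "")
  tx_seq <- paste0(up, intron, dn)
  l1 <- nchar(up); l2 <- nchar(dn); total <- nchar(tx_seq)
  if (strand == "+") {
    chrom_seq <- tx_seq
    e1 <- c(0L, l1); iv <- c(l1, l1 + L); e2 <- c(l1 + L, total)
  } else {
    chrom_seq <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(tx_seq)))
    e1 <- c(total - l1, total); iv <- c(l2, total - l1); e2 <- c(0L, l2)
  }
  genome <- tiny_genome(list(c1 = chrom_seq))
  tx <- tiny_tx(if (strand == "+") list(e1, e2) else list(e2, e1),
                strand = strand, chrom = "c1",
                cds = if (strand == "+") list(e1, e2) else list(e2, e1))
  list(tx = tx, genome = genome, intron = iv,
       up_cds = up, down_cds = dn, intron_seq = intron)
}

# Independent oracle: translate the retained-intron coding sequence and
# locate the first stop codon.
oracle_ri_consequence <- function(up_cds, intron_seq, down_cds) {
  mut <- paste0(up_cds, intron_seq, down_cds)
  n_cod <- nchar(mut) %/% 3L
  aa <- as.character(Biostrings::translate(
    Biostrings::DNAString(substr(mut, 1, 3 * n_cod)), no.init.codon = TRUE))
  stop_at <- regexpr("*", aa, fixed = TRUE)[1]
  if (stop_at < 0) return("no_ptc")
  span <- c(3L * (stop_at - 1L) + 1L, 3L * stop_at)  # nt positions of stop
  intron_span <- c(nchar(up_cds) + 1L, nchar(up_cds) + nchar(intron_seq))
  if (span[1] <= intron_span[2] && span[2] >= intron_span[1])
    "in_frame_stop"
  else
    "frameshift_ptc_downstream"
}
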