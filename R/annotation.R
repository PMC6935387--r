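#' @import Biostrings
#' @importFrom S4Vectors mcols
#' @importFrom stats setNames
NULL

# Chromosome names treated as mitochondrial unless the caller overrides them.
DEFAULT_MITO_CHROMS <- c("chrM", "MT", "chrMT")

#' Load a genome FASTA
#'
#' Reads a (multi-record) FASTA into a named [Biostrings::DNAStringSet].
#' Sequences are uppercased and any IUPAC ambiguity code other than `N`
#' is replaced by `N` (with a warning giving the substitution count).
#'
#' @param fasta_path Path to a FASTA file.
#' @return A `DNAStringSet`, one element per chromosome. Record names are
#'   truncated at the first whitespace.
#' @export
load_genome <- function(fasta_path) {
  if (!file.exists(fasta_path)) stop("FASTA file not found: ", fasta_path)
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  if (length(seqs) == 0L) stop("FASTA file is empty: ", fasta_path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(names(seqs)))
    stop("duplicate FASTA record name(s): ",
         paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "))
  raw <- toupper(as.character(seqs))
  n_amb <- sum(vapply(raw, function(s) {
    sum(charToRaw(s) %in% charToRaw("RYSWKMBDHV"))
  }, numeric(1)))
  if (n_amb > 0) {
    warning(n_amb, " ambiguity base(s) other than N replaced by N")
    raw <- chartr("RYSWKMBDHV", strrep("N", 10L), raw)
  }
  out <- Biostrings::DNAStringSet(raw)
  names(out) <- names(seqs)
  out
}

#' Chromosome lengths of a loaded genome
#' @param genome A `DNAStringSet` from [load_genome()].
#' @return Named integer vector of lengths in bp.
#' @export
genome_lengths <- function(genome) {
  setNames(Biostrings::width(genome), names(genome))
}

#' Load a GTF gene annotation
#'
#' Parses a Gencode-style GTF (exon and optional CDS features with quoted
#' `gene_id`/`transcript_id` attributes) into a list of gene models. All
#' internal coordinates are 0-based half-open; conversion from the GTF's
#' 1-based closed convention happens here and only here.
#'
#' @param gtf_path Path to a GTF file.
#' @param mito_chroms Chromosome names regarded as mitochondrial.
#' @return An object of class `sp_annotation`: a list with element `genes`,
#'   a named list of gene models. Each gene model carries `gene_id`,
#'   `gene_name`, `chrom`, `strand`, `biotype`, `is_mitochondrial` and a list
#'   of transcript models (`exons` as an n x 2 matrix of `[start, end)`
#'   intervals sorted by genomic coordinate, `cds` likewise with a `phase`
#'   column, `biotype`, and integer `tsl` or `NA`).
#' @export
load_annotation <- function(gtf_path, mito_chroms = DEFAULT_MITO_CHROMS) {
  if (!file.exists(gtf_path)) stop("GTF file not found: ", gtf_path)
  gr <- rtracklayer::import(gtf_path, format = "gtf")
  md <- S4Vectors::mcols(gr)
  keep <- md$type %in% c("exon", "CDS")
  gr <- gr[keep]
  md <- S4Vectors::mcols(gr)
  if (length(gr) == 0L) stop("GTF contains no exon features: ", gtf_path)

  df <- data.frame(
    type = as.character(md$type),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    # internal 0-based half-open
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    gene_id = as.character(md$gene_id),
    transcript_id = if (!is.null(md$transcript_id)) as.character(md$transcript_id) else NA_character_,
    stringsAsFactors = FALSE
  )
  if (any(df$end < df$start + 1L))
    stop("GTF feature with end < start")
  if (any(df$type == "exon" & (is.na(df$transcript_id) | df$transcript_id == "")))
    stop("exon feature lacking transcript_id")

  df$gene_name <- .gtf_attr(md, "gene_name", df$gene_id)
  df$gene_type <- .gtf_attr(md, "gene_type", NA_character_)
  if (all(is.na(df$gene_type))) df$gene_type <- .gtf_attr(md, "gene_biotype", NA_character_)
  df$transcript_type <- .gtf_attr(md, "transcript_type", NA_character_)
  if (all(is.na(df$transcript_type))) df$transcript_type <- .gtf_attr(md, "transcript_biotype", NA_character_)
  tsl_raw <- .gtf_attr(md, "transcript_support_level", NA_character_)
  df$tsl <- suppressWarnings(as.integer(sub("\\s.*$", "", tsl_raw)))
  df$phase <- if (!is.null(md$phase)) suppressWarnings(as.integer(as.character(md$phase))) else NA_integer_

  genes <- vector("list", 0L)
  n_dropped <- 0L
  for (gid in unique(df$gene_id)) {
    g <- df[df$gene_id == gid, , drop = FALSE]
    txs <- list()
    for (tid in unique(g$transcript_id[!is.na(g$transcript_id)])) {
      t <- g[g$transcript_id == tid, , drop = FALSE]
      ex <- t[t$type == "exon", , drop = FALSE]
      if (nrow(ex) == 0L) { n_dropped <- n_dropped + 1L; next }
      ord <- order(ex$start)
      exons <- cbind(start = ex$start[ord], end = ex$end[ord])
      if (any(exons[-1, "start", drop = TRUE] < exons[-nrow(exons), "end", drop = TRUE]))
        stop("overlapping exons in transcript ", tid)
      cds_rows <- t[t$type == "CDS", , drop = FALSE]
      cds <- NULL
      if (nrow(cds_rows) > 0L) {
        ordc <- order(cds_rows$start)
        cds <- cbind(start = cds_rows$start[ordc], end = cds_rows$end[ordc],
                     phase = cds_rows$phase[ordc])
      }
      txs[[tid]] <- list(
        gene_id = gid, transcript_id = tid,
        chrom = ex$chrom[1], strand = ex$strand[1],
        biotype = if (!is.na(ex$transcript_type[1])) ex$transcript_type[1] else ex$gene_type[1],
        tsl = ex$tsl[1],
        exons = exons, cds = cds
      )
    }
    genes[[gid]] <- list(
      gene_id = gid,
      gene_name = g$gene_name[1],
      chrom = g$chrom[1],
      strand = g$strand[1],
      biotype = g$gene_type[1],
      is_mitochondrial = g$chrom[1] %in% mito_chroms,
      transcripts = txs
    )
  }
  if (n_dropped > 0L)
    warning(n_dropped, " transcript(s) without exons dropped")
  structure(list(genes = genes, mito_chroms = mito_chroms),
            class = "sp_annotation")
}

.gtf_attr <- function(md, name, default) {
  if (!is.null(md[[name]])) {
    v <- as.character(md[[name]])
    v[is.na(v)] <- NA_character_
    v
  } else {
    rep(if (length(default) == 1L) default else NA_character_, nrow(md))
  }
}

#' @export
print.sp_annotation <- function(x, ...) {
  cat("sp_annotation:", length(x$genes), "genes,",
      sum(vapply(x$genes, function(g) length(g$transcripts), integer(1))),
      "transcripts\n")
  invisible(x)
}

#' Select a gene's reference transcript
#'
#' The reference transcript is the longest protein-coding transcript that has
#' a parsed transcript support level (TSL). "Longest" means summed exon
#' (mature transcript) length. Ties are broken by lowest TSL, then by
#' lexicographically smallest transcript id. Transcripts whose TSL attribute
#' is missing or "NA" do not qualify.
#'
#' @param gene A gene model from [load_annotation()].
#' @return A transcript model, or `NULL` if no transcript qualifies.
#' @export
select_reference_transcript <- function(gene) {
  txs <- Filter(function(t) identical(t$biotype, "protein_coding") && !is.na(t$tsl),
                gene$transcripts)
  if (length(txs) == 0L) return(NULL)
  len <- vapply(txs, tx_spliced_length, numeric(1))
  tsl <- vapply(txs, function(t) as.numeric(t$tsl), numeric(1))
  tid <- vapply(txs, function(t) t$transcript_id, character(1))
  ord <- order(-len, tsl, tid)
  txs[[ord[1L]]]
}

#' Summed exon length of a transcript
#' @param tx A transcript model.
#' @return Mature transcript length in nt.
#' @export
tx_spliced_length <- function(tx) {
  sum(tx$exons[, "end"] - tx$exons[, "start"])
}

#' Introns of a transcript
#'
#' @param tx A transcript model.
#' @return An n x 2 matrix of `[start, end)` intron intervals in genomic
#'   order (gaps between consecutive exons); zero rows for single-exon
#'   transcripts.
#' @export
tx_introns <- function(tx) {
  ex <- tx$exons
  n <- nrow(ex)
  if (n < 2L) return(cbind(start = integer(0), end = integer(0)))
  cbind(start = ex[-n, "end"], end = ex[-1, "start"])
}

#' Extract strand-aware sequence
#'
#' @param genome A `DNAStringSet` from [load_genome()].
#' @param chrom Chromosome name.
#' @param start,end 0-based half-open genomic interval.
#' @param strand `"+"` or `"-"`; minus returns the reverse complement, i.e.
#'   the transcript-orientation sequence of a minus-strand feature.
#' @return A character scalar of length `end - start`.
#' @export
get_sequence <- function(genome, chrom, start, end, strand = "+") {
  if (!chrom %in% names(genome)) stop("unknown chromosome: ", chrom)
  x <- genome[[chrom]]
  L <- length(x)
  if (start < 0 || end > L || end < start)
    stop("interval [", start, ",", end, ") out of bounds for ", chrom, " (", L, " bp)")
  s <- Biostrings::subseq(x, start = start + 1L, end = end)
  if (strand == "-") s <- Biostrings::reverseComplement(s)
  as.character(s)
}

#' Reverse complement of a character sequence
#' @param seq Character vector of DNA strings (A/C/G/T/N).
#' @return Reverse-complemented strings.
#' @export
revcomp <- function(seq) {
  vapply(seq, function(s)
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s))),
    character(1), USE.NAMES = FALSE)
}
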