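# Donor/acceptor positional log-odds models and branch-point prediction.
#
# Window conventions follow the MaxEntScan tools so externally published
# score tables plug in without re-indexing:
#   donor    9-mer: last 3 exonic nt + first 6 intronic nt
#   acceptor 23-mer: last 20 intronic nt + first 3 exonic nt

DONOR_WINDOW <- 9L
ACCEPTOR_WINDOW <- 23L
DNA_BASES <- c("A", "C", "G", "T")

.window_len <- function(site_kind) {
  switch(site_kind, donor = DONOR_WINDOW, acceptor = ACCEPTOR_WINDOW,
         stop("site_kind must be 'donor' or 'acceptor'"))
}

#' Strand-symmetric mononucleotide background of a genome
#'
#' Base frequencies with each base's count averaged with its complement's
#' (A with T, C with G), N excluded. The symmetrization makes trained models
#' invariant under reverse-complementing the genome together with its
#' annotation, which is the natural requirement for a double-stranded
#' substrate.
#'
#' @param genome `DNAStringSet`.
#' @return Named numeric vector over A/C/G/T summing to 1.
#' @export
genome_background <- function(genome) {
  counts <- colSums(Biostrings::alphabetFrequency(genome)[, DNA_BASES, drop = FALSE])
  sym <- c(A = (counts[["A"]] + counts[["T"]]) / 2,
           C = (counts[["C"]] + counts[["G"]]) / 2,
           G = (counts[["C"]] + counts[["G"]]) / 2,
           T = (counts[["A"]] + counts[["T"]]) / 2)
  sym / sum(sym)
}

#' Uniform base background
#' @return Named numeric vector, each base 0.25.
#' @export
uniform_background <- function() setNames(rep(0.25, 4), DNA_BASES)

# Donor/acceptor window around an intron [s,e) on `strand`, in transcript
# orientation. Donor: 3 exonic + 6 intronic; acceptor: 20 intronic + 3 exonic.
.site_window_coords <- function(start, end, strand, site_kind) {
  if (site_kind == "donor") {
    if (strand == "+") c(start - 3L, start + 6L) else c(end - 6L, end + 3L)
  } else {
    if (strand == "+") c(end - 20L, end + 3L) else c(start - 3L, start + 20L)
  }
}

#' Extract a splice-site window sequence
#'
#' @param genome `DNAStringSet`.
#' @param chrom Chromosome.
#' @param intron_start,intron_end 0-based half-open intron interval.
#' @param strand `"+"` or `"-"`.
#' @param site_kind `"donor"` or `"acceptor"`.
#' @return Character scalar (9 or 23 nt) in transcript orientation.
#' @export
site_window <- function(genome, chrom, intron_start, intron_end, strand, site_kind) {
  w <- .site_window_coords(intron_start, intron_end, strand, site_kind)
  get_sequence(genome, chrom, w[1], w[2], strand)
}

#' Collect splice-site training windows from an annotation
#'
#' Walks every intron of every gene's reference transcript (unique by
#' chromosome, strand and coordinates), keeps GT..AG-flanked introns, and
#' extracts the donor or acceptor window. Windows containing N, introns
#' shorter than the intronic part of the window, and non-canonical introns
#' are skipped with counts reported in the attributes `n_skipped_n`,
#' `n_skipped_short` and `n_skipped_noncanonical`.
#'
#' @param annotation Annotation object.
#' @param genome `DNAStringSet`.
#' @param site_kind `"donor"` or `"acceptor"`.
#' @param canonical_only Keep only GT..AG introns (default TRUE).
#' @return Character vector of window sequences.
#' @export
collect_training_sites <- function(annotation, genome, site_kind = c("donor", "acceptor"),
                                   canonical_only = TRUE) {
  site_kind <- match.arg(site_kind)
  intronic_need <- if (site_kind == "donor") 6L else 20L
  seen <- new.env(hash = TRUE)
  windows <- character(0)
  n_n <- 0L; n_short <- 0L; n_noncanon <- 0L
  for (gene in annotation$genes) {
    tx <- select_reference_transcript(gene)
    if (is.null(tx)) next
    introns <- tx_introns(tx)
    if (nrow(introns) == 0L) next
    # iterate in transcript order so collection is mirror-stable
    rows <- if (tx$strand == "+") seq_len(nrow(introns)) else rev(seq_len(nrow(introns)))
    for (r in rows) {
      s <- introns[r, "start"]; e <- introns[r, "end"]
      key <- paste(tx$chrom, tx$strand, s, e, sep = ":")
      if (!is.null(seen[[key]])) next
      seen[[key]] <- TRUE
      if (e - s < max(intronic_need, 4L)) { n_short <- n_short + 1L; next }
      if (canonical_only) {
        iseq_ends <- paste0(get_sequence(genome, tx$chrom, s, s + 2L, tx$strand),
                            get_sequence(genome, tx$chrom, e - 2L, e, tx$strand))
        if (tx$strand == "-") {
          iseq_ends <- paste0(get_sequence(genome, tx$chrom, e - 2L, e, tx$strand),
                              get_sequence(genome, tx$chrom, s, s + 2L, tx$strand))
        }
        if (iseq_ends != "GTAG") { n_noncanon <- n_noncanon + 1L; next }
      }
      w <- tryCatch(site_window(genome, tx$chrom, s, e, tx$strand, site_kind),
                    error = function(e) NA_character_)
      if (is.na(w)) { n_short <- n_short + 1L; next }
      if (grepl("[^ACGT]", w)) { n_n <- n_n + 1L; next }
      windows <- c(windows, w)
    }
  }
  attr(windows, "n_skipped_n") <- n_n
  attr(windows, "n_skipped_short") <- n_short
  attr(windows, "n_skipped_noncanonical") <- n_noncanon
  windows
}

#' Train a positional log-odds splice-site model
#'
#' Per-position base probabilities with additive pseudocount:
#' `probs[p, b] = (count[p, b] + pseudocount) / (N + 4 * pseudocount)`.
#'
#' @param windows Character vector of equal-length A/C/G/T windows.
#' @param site_kind `"donor"` (9 nt) or `"acceptor"` (23 nt).
#' @param pseudocount Additive smoothing, default 0.5.
#' @param background Named base-probability vector (e.g.
#'   [genome_background()]); default uniform.
#' @return Object of class `splice_site_model` with elements `site_kind`,
#'   `window`, `counts`, `probs`, `background`, `pseudocount`, `n_train`.
#' @export
train_splice_model <- function(windows, site_kind = c("donor", "acceptor"),
                               pseudocount = 0.5,
                               background = uniform_background()) {
  site_kind <- match.arg(site_kind)
  wlen <- .window_len(site_kind)
  if (length(windows) == 0L) stop("no training windows")
  if (any(nchar(windows) != wlen))
    stop("training windows must all be ", wlen, " nt for ", site_kind)
  if (any(grepl("[^ACGT]", windows)))
    stop("training windows must contain only A/C/G/T")
  mat <- do.call(rbind, strsplit(windows, ""))
  counts <- vapply(seq_len(wlen), function(p)
    tabulate(factor(mat[, p], levels = DNA_BASES), nbins = 4L), numeric(4))
  counts <- t(counts)  # position x base
  colnames(counts) <- DNA_BASES
  probs <- (counts + pseudocount) / (length(windows) + 4 * pseudocount)
  background <- background[DNA_BASES] / sum(background[DNA_BASES])
  structure(list(site_kind = site_kind, window = wlen,
                 counts = counts, probs = probs,
                 background = background, pseudocount = pseudocount,
                 n_train = length(windows)),
            class = "splice_site_model")
}

#' @export
print.splice_site_model <- function(x, ...) {
  cat("splice_site_model:", x$site_kind, "(", x$window, "nt ),",
      x$n_train, "training sites, pseudocount", x$pseudocount, "\n")
  invisible(x)
}

#' Score splice-site windows
#'
#' Position-independent log-odds in bits:
#' `score = sum_p log2(probs[p, base_p] / background[base_p])`.
#' Group comparisons of these scores, not their absolute values, are the
#' supported contract.
#'
#' @param model A `splice_site_model` or a lookup scorer from
#'   [load_external_score_tables()].
#' @param windows Character vector of windows (A/C/G/T, model's length).
#' @return Numeric vector of scores in bits (table scores for a lookup
#'   scorer).
#' @export
score_site <- function(model, windows) UseMethod("score_site")

#' @export
score_site.splice_site_model <- function(model, windows) {
  if (length(windows) == 0L) return(numeric(0))
  if (any(nchar(windows) != model$window))
    stop("window length must be ", model$window, " for ", model$site_kind)
  if (any(grepl("[^ACGT]", windows)))
    stop("windows must contain only A/C/G/T")
  lod <- log2(sweep(model$probs, 2, model$background, "/"))
  vapply(strsplit(windows, ""), function(b)
    sum(lod[cbind(seq_along(b), match(b, DNA_BASES))]), numeric(1))
}

#' Load an external k-mer score table
#'
#' Optional parity mode: a plain-text table mapping each window k-mer to a
#' published score (one `NMER<tab>SCORE` per line, no header). Scoring is a
#' straight lookup; absent k-mers are an error.
#'
#' @param path Path to the table.
#' @return Object of class `splice_score_table` usable with [score_site()].
#' @export
load_external_score_tables <- function(path) {
  if (!file.exists(path)) stop("score table not found: ", path)
  tab <- utils::read.delim(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE,
                           col.names = c("kmer", "score"))
  if (nrow(tab) == 0L) stop("empty score table: ", path)
  tab$score <- as.numeric(tab$score)
  if (any(is.na(tab$score)) || any(!grepl("^[ACGT]+$", tab$kmer)))
    stop("malformed score table: ", path)
  if (length(unique(nchar(tab$kmer))) != 1L)
    stop("score table k-mers have mixed lengths: ", path)
  structure(list(scores = setNames(tab$score, tab$kmer),
                 window = nchar(tab$kmer[1])),
            class = "splice_score_table")
}

#' @export
score_site.splice_score_table <- function(model, windows) {
  if (length(windows) == 0L) return(numeric(0))
  if (any(nchar(windows) != model$window))
    stop("window length must be ", model$window)
  s <- model$scores[windows]
  if (any(is.na(s)))
    stop("k-mer(s) absent from score table: ",
         paste(unique(windows[is.na(s)]), collapse = ", "))
  unname(s)
}

#' Built-in branch-point consensus weight matrix
#'
#' A fixed 7 x 4 log2-odds weight table (versus uniform background) for the
#' 7-mer around the branch adenosine (the A is position 5), encoding an
#' extended pyrimidine-rich branch consensus of the TACTAAC type with
#' strong weight on the branch A and the -1 U.
#'
#' @return 7 x 4 numeric matrix, columns A/C/G/T.
#' @export
branch_point_matrix <- function() {
  m <- rbind(
    c(-0.5,  0.5, -1.0,  1.0),   # pos 1
    c( 0.8,  0.0, -1.0,  0.3),   # pos 2
    c(-0.5,  1.0, -1.0,  0.3),   # pos 3
    c( 0.0,  0.0, -0.5,  1.2),   # pos 4 (U of yUnAy)
    c( 2.0, -4.0, -4.0, -4.0),   # pos 5: branch A
    c( 1.2, -0.5,  0.5, -0.5),   # pos 6
    c(-0.5,  0.8, -0.5,  0.5)    # pos 7
  )
  colnames(m) <- DNA_BASES
  m
}

#' Predict the branch point of an intron
#'
#' Scans every adenosine whose distance to the intron's 3' end (the
#' BPS-3'SS distance) lies in `[search_min, min(search_max, len) - 1]` and
#' scores the 7-mer with the A at position 5 using the built-in consensus
#' matrix, plus `ppt_weight` times the pyrimidine fraction of the
#' `ppt_window` nt immediately 3' of the A (the polypyrimidine tract). The
#' top-scoring candidate wins; ties go to the candidate closest to the 3'
#' splice site.
#'
#' @param intron_seq Intron sequence 5'->3' (transcript orientation).
#' @param search_min,search_max Offset window from the 3' end, defaults 15
#'   and 500 nt.
#' @param ppt_window PPT window size 3' of the branch A, default 25 nt.
#' @param ppt_weight Weight (bits) of the PPT fraction, default 2.
#' @return A list with `bp_offset` (nt from branch A to intron 3' end),
#'   `score`, `sequence_context` (the 7-mer), `ppt_score`; or `NULL` when
#'   the intron is too short or has no candidate A.
#' @export
find_branch_point <- function(intron_seq, search_min = 15L, search_max = 500L,
                              ppt_window = 25L, ppt_weight = 2.0) {
  L <- nchar(intron_seq)
  if (L < search_min + 7L) return(NULL)
  b <- strsplit(intron_seq, "")[[1]]
  # candidate A positions (1-based, 5'->3'); offset = L - pos
  pos <- which(b == "A")
  off <- L - pos
  keep <- off >= search_min & off <= min(search_max, L) - 1L & pos >= 5L & pos <= L - 2L
  pos <- pos[keep]; off <- off[keep]
  if (length(pos) == 0L) return(NULL)
  wm <- branch_point_matrix()
  base_idx <- match(b, DNA_BASES)
  pwm_scores <- vapply(pos, function(p) {
    idx <- base_idx[(p - 4L):(p + 2L)]
    if (anyNA(idx)) return(-Inf)  # N in context
    sum(wm[cbind(1:7, idx)])
  }, numeric(1))
  ppt <- vapply(pos, function(p) {
    w <- b[(p + 1L):min(L, p + ppt_window)]
    mean(w %in% c("C", "T"))
  }, numeric(1))
  total <- pwm_scores + ppt_weight * ppt
  if (all(!is.finite(total))) return(NULL)
  best <- which(total == max(total))
  # tie-break: closest to the 3'SS (smallest offset)
  best <- best[which.min(off[best])]
  list(bp_offset = off[best],
       score = total[best],
       sequence_context = paste(b[(pos[best] - 4L):(pos[best] + 2L)], collapse = ""),
       ppt_score = ppt[best])
}
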