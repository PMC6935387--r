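# Per-item feature vectors for events and control constructs: splice-site
# strengths, lengths, GC, BPS-3'SS distances, and the coding consequence of
# intron retention.

#' GC content of a sequence
#'
#' `(#G + #C) / (#A + #C + #G + #T)`; N bases are excluded from both
#' numerator and denominator.
#'
#' @param seq Character scalar.
#' @return Fraction in `[0, 1]`; error on empty or all-N input.
#' @export
gc_content <- function(seq) {
  if (length(seq) != 1L || is.na(seq) || nchar(seq) == 0L)
    stop("gc_content needs one nonempty sequence")
  b <- strsplit(seq, "")[[1]]
  n_acgt <- sum(b %in% c("A", "C", "G", "T"))
  if (n_acgt == 0L) stop("sequence contains no A/C/G/T bases")
  sum(b %in% c("G", "C")) / n_acgt
}

#' Classify the coding consequence of retaining an intron
#'
#' Computes the codon phase at the intron insertion point from the CDS
#' annotation and scans the retained intron (including the codons spanning
#' its junctions) in that frame for TAA/TAG/TGA. If none is found and the
#' intron length is not a multiple of 3, scanning continues in the shifted
#' frame through the remaining exonic CDS up to the transcript's annotated
#' stop; a premature stop there is a frameshift PTC. A frame-preserving
#' intron with no stop is potentially functional (`no_ptc`).
#'
#' @param tx Transcript model with CDS.
#' @param intron Length-2 vector `[start, end)`; must be an annotated intron
#'   of `tx`.
#' @param genome `DNAStringSet`.
#' @return One of `"in_frame_stop"`, `"frameshift_ptc_downstream"`,
#'   `"no_ptc"`, `"frame_unavailable"`.
#' @export
classify_ri_consequence <- function(tx, intron, genome) {
  introns <- tx_introns(tx)
  hit <- which(introns[, "start"] == intron[1] & introns[, "end"] == intron[2])
  if (length(hit) != 1L)
    stop("interval [", intron[1], ",", intron[2], ") is not an intron of ",
         tx$transcript_id)
  if (is.null(tx$cds)) return("frame_unavailable")
  cds <- tx$cds
  # intron must lie strictly inside the CDS genomic span
  if (intron[1] < min(cds[, "start"]) || intron[2] > max(cds[, "end"]))
    return("frame_unavailable")

  # CDS pieces in transcript order, as sequences
  ord <- if (tx$strand == "+") seq_len(nrow(cds)) else rev(seq_len(nrow(cds)))
  pieces <- vapply(ord, function(i)
    get_sequence(genome, tx$chrom, cds[i, "start"], cds[i, "end"], tx$strand),
    character(1))
  # number of CDS pieces upstream (transcript 5') of the intron
  if (tx$strand == "+") {
    n_up <- sum(cds[, "end"] <= intron[1])
    ok <- any(cds[, "end"] == intron[1]) && any(cds[, "start"] == intron[2])
  } else {
    n_up <- sum(cds[, "start"] >= intron[2])
    ok <- any(cds[, "start"] == intron[2]) && any(cds[, "end"] == intron[1])
  }
  if (!ok) return("frame_unavailable")  # intron not flanked by coding sequence

  up_cds <- paste(pieces[seq_len(n_up)], collapse = "")
  down_cds <- paste(pieces[setdiff(seq_along(pieces), seq_len(n_up))], collapse = "")
  intron_seq <- get_sequence(genome, tx$chrom, intron[1], intron[2], tx$strand)
  L <- nchar(intron_seq)
  phase <- nchar(up_cds) %% 3L

  # codons overlapping the intron: phase leftover exonic nt + intron + the
  # downstream nt needed to complete the last codon
  carry <- if (phase > 0L) substr(up_cds, nchar(up_cds) - phase + 1L, nchar(up_cds)) else ""
  need <- (3L - (phase + L) %% 3L) %% 3L
  tailseq <- if (need > 0L) substr(down_cds, 1L, need) else ""
  scan1 <- paste0(carry, intron_seq, tailseq)
  if (.has_stop_in_frame(scan1)) return("in_frame_stop")

  if (L %% 3L == 0L) return("no_ptc")
  # shifted frame continues into the remaining downstream CDS
  rest <- substr(down_cds, need + 1L, nchar(down_cds))
  if (.has_stop_in_frame(rest)) "frameshift_ptc_downstream" else "no_ptc"
}

.has_stop_in_frame <- function(seq) {
  n <- nchar(seq)
  if (n < 3L) return(FALSE)
  starts <- seq(1L, n - 2L, by = 3L)
  codons <- substring(seq, starts, starts + 2L)
  any(codons %in% c("TAA", "TAG", "TGA"))
}

# Resolve an item (RI/SE event row or construct) to its anatomy in
# transcript order. Returns NULL components where not applicable.
.ri_anatomy <- function(item) {
  if (inherits(item, "sp_construct")) {
    seg <- item$segments
    list(chrom = item$chrom, strand = item$strand,
         gene_id = item$gene_id, transcript_id = item$transcript_id,
         up_exon = c(seg$start[1], seg$end[1]),
         intron = c(seg$start[2], seg$end[2]),
         down_exon = c(seg$start[3], seg$end[3]),
         item_id = paste0(item$origin, "_", item$gene_id, "_", item$first_exon))
  } else {
    # rMATS upstream/downstream flanks are already transcript-relative
    list(chrom = item$chrom, strand = item$strand,
         gene_id = item$gene_id, transcript_id = NA_character_,
         up_exon = c(item$upstream_es, item$upstream_ee),
         intron = c(item$intron_start, item$intron_end),
         down_exon = c(item$downstream_es, item$downstream_ee),
         item_id = item$event_id)
  }
}

# NOTE on orientation: segment/coordinate slots are genomic; "upstream"
# below always means transcript-5'. For constructs the segments are already
# in transcript order; for rMATS rows upstream/downstream are genomic and
# are swapped on the minus strand.

.se_anatomy <- function(item) {
  if (inherits(item, "sp_construct")) {
    seg <- item$segments
    list(chrom = item$chrom, strand = item$strand,
         gene_id = item$gene_id, transcript_id = item$transcript_id,
         up_exon = c(seg$start[1], seg$end[1]),
         up_intron = c(seg$start[2], seg$end[2]),
         focal = c(seg$start[3], seg$end[3]),
         down_intron = c(seg$start[4], seg$end[4]),
         down_exon = c(seg$start[5], seg$end[5]),
         item_id = paste0(item$origin, "_", item$gene_id, "_", item$first_exon))
  } else {
    # rMATS upstream/downstream flanks are already transcript-relative;
    # on the minus strand the transcript-upstream exon is genomic-right
    up <- c(item$upstream_es, item$upstream_ee)
    dn <- c(item$downstream_es, item$downstream_ee)
    focal <- c(item$exon_start, item$exon_end)
    if (item$strand == "+") {
      up_in <- c(up[2], focal[1]); down_in <- c(focal[2], dn[1])
    } else {
      up_in <- c(focal[2], up[1]); down_in <- c(dn[2], focal[1])
    }
    list(chrom = item$chrom, strand = item$strand,
         gene_id = item$gene_id, transcript_id = NA_character_,
         up_exon = up, up_intron = up_in, focal = focal,
         down_intron = down_in, down_exon = dn,
         item_id = item$event_id)
  }
}

.safe_score <- function(model, genome, chrom, s, e, strand, kind) {
  w <- tryCatch(site_window(genome, chrom, s, e, strand, kind),
                error = function(err) NA_character_)
  if (is.na(w) || grepl("[^ACGT]", w)) return(NA_real_)
  score_site(model, w)
}

.bp_offset_of <- function(genome, chrom, s, e, strand, bp_params) {
  seqi <- get_sequence(genome, chrom, s, e, strand)
  bp <- do.call(find_branch_point, c(list(seqi), bp_params))
  if (is.null(bp)) NA_integer_ else bp$bp_offset
}

#' Extract the feature vector of a retained-intron item
#'
#' Works for an RI event row or an E-I-E control construct. Donor and
#' acceptor are the focal intron's own sites; the BPS-3'SS distance comes
#' from [find_branch_point()] on the transcript-orientation intron
#' sequence. The coding consequence is classified when the item can be
#' resolved to an annotated intron of a CDS-bearing transcript, otherwise
#' `frame_unavailable`.
#'
#' @param item One-row RI event data frame, or construct.
#' @param genome `DNAStringSet`.
#' @param models List with `donor` and `acceptor` splice-site models.
#' @param annotation Annotation object.
#' @param group Group label (IRI/DRI/ICI/ECI).
#' @param bp_params Optional list of [find_branch_point()] arguments.
#' @return One-row data frame of features. Splice scores are `NA` (item
#'   flagged via `n_in_window`) when a scoring window contains N.
#' @export
extract_ri_features <- function(item, genome, models, annotation,
                                group = NA_character_, bp_params = list()) {
  a <- .ri_anatomy(item)
  intron_seq <- get_sequence(genome, a$chrom, a$intron[1], a$intron[2], a$strand)
  donor <- .safe_score(models$donor, genome, a$chrom, a$intron[1], a$intron[2],
                       a$strand, "donor")
  acceptor <- .safe_score(models$acceptor, genome, a$chrom, a$intron[1], a$intron[2],
                          a$strand, "acceptor")
  consequence <- "frame_unavailable"
  tid <- a$transcript_id
  gene <- annotation$genes[[a$gene_id]]
  tx <- if (!is.null(gene)) select_reference_transcript(gene) else NULL
  if (!is.null(tx)) {
    introns <- tx_introns(tx)
    if (any(introns[, "start"] == a$intron[1] & introns[, "end"] == a$intron[2])) {
      consequence <- classify_ri_consequence(tx, a$intron, genome)
      tid <- tx$transcript_id
    }
  }
  data.frame(
    item_id = a$item_id, group = group,
    gene_id = a$gene_id, transcript_id = tid,
    chrom = a$chrom, strand = a$strand,
    intron_start = a$intron[1], intron_end = a$intron[2],
    donor_score = donor, acceptor_score = acceptor,
    focal_length = a$intron[2] - a$intron[1],
    focal_gc = gc_content(intron_seq),
    upstream_exon_len = a$up_exon[2] - a$up_exon[1],
    downstream_exon_len = a$down_exon[2] - a$down_exon[1],
    bp_offset = .bp_offset_of(genome, a$chrom, a$intron[1], a$intron[2],
                              a$strand, bp_params),
    ri_consequence = consequence,
    n_in_window = is.na(donor) || is.na(acceptor),
    stringsAsFactors = FALSE
  )
}

#' Extract the feature vector of a skipped-exon item
#'
#' Works for an SE event row or an E-I-E-I-E control construct.
#' `donor_score`/`acceptor_score` are the focal exon's own 5'SS and 3'SS;
#' `upstream_donor_score` is the donor of the upstream flanking exon and
#' `downstream_acceptor_score` the acceptor feeding the downstream flanking
#' exon. BPS-3'SS distances are computed for both flanking introns.
#'
#' @inheritParams extract_ri_features
#' @param group Group label (ISE/DSE/ICE/ECE).
#' @return One-row data frame of features.
#' @export
extract_se_features <- function(item, genome, models, annotation,
                                group = NA_character_, bp_params = list()) {
  a <- .se_anatomy(item)
  focal_seq <- get_sequence(genome, a$chrom, a$focal[1], a$focal[2], a$strand)
  up_in_seq <- get_sequence(genome, a$chrom, a$up_intron[1], a$up_intron[2], a$strand)
  down_in_seq <- get_sequence(genome, a$chrom, a$down_intron[1], a$down_intron[2], a$strand)
  donor <- .safe_score(models$donor, genome, a$chrom, a$down_intron[1],
                       a$down_intron[2], a$strand, "donor")
  acceptor <- .safe_score(models$acceptor, genome, a$chrom, a$up_intron[1],
                          a$up_intron[2], a$strand, "acceptor")
  up_donor <- .safe_score(models$donor, genome, a$chrom, a$up_intron[1],
                          a$up_intron[2], a$strand, "donor")
  down_acceptor <- .safe_score(models$acceptor, genome, a$chrom, a$down_intron[1],
                               a$down_intron[2], a$strand, "acceptor")
  data.frame(
    item_id = a$item_id, group = group,
    gene_id = a$gene_id, transcript_id = a$transcript_id,
    chrom = a$chrom, strand = a$strand,
    exon_start = a$focal[1], exon_end = a$focal[2],
    donor_score = donor, acceptor_score = acceptor,
    upstream_donor_score = up_donor,
    downstream_acceptor_score = down_acceptor,
    focal_length = a$focal[2] - a$focal[1],
    focal_gc = gc_content(focal_seq),
    upstream_intron_len = a$up_intron[2] - a$up_intron[1],
    downstream_intron_len = a$down_intron[2] - a$down_intron[1],
    upstream_intron_gc = gc_content(up_in_seq),
    downstream_intron_gc = gc_content(down_in_seq),
    bp_offset_upstream = .bp_offset_of(genome, a$chrom, a$up_intron[1],
                                       a$up_intron[2], a$strand, bp_params),
    bp_offset_downstream = .bp_offset_of(genome, a$chrom, a$down_intron[1],
                                         a$down_intron[2], a$strand, bp_params),
    n_in_window = is.na(donor) || is.na(acceptor) || is.na(up_donor) ||
      is.na(down_acceptor),
    stringsAsFactors = FALSE
  )
}

#' Feature table for a set of RI items
#'
#' @param events Direction-classified RI events (may be empty).
#' @param internal,external Lists of E-I-E constructs.
#' @param genome,models,annotation,bp_params As in [extract_ri_features()].
#' @return Data frame, one row per item, grouped IRI/DRI/ICI/ECI.
#' @export
ri_feature_table <- function(events, internal, external, genome, models,
                             annotation, bp_params = list()) {
  rows <- list()
  if (!is.null(events) && nrow(events) > 0L) {
    for (i in seq_len(nrow(events))) {
      ev <- events[i, ]
      rows[[length(rows) + 1L]] <- extract_ri_features(
        ev, genome, models, annotation,
        group = event_group_label("RI", ev$direction), bp_params = bp_params)
    }
  }
  for (cc in internal)
    rows[[length(rows) + 1L]] <- extract_ri_features(cc, genome, models,
                                                     annotation, "ICI", bp_params)
  for (cc in external)
    rows[[length(rows) + 1L]] <- extract_ri_features(cc, genome, models,
                                                     annotation, "ECI", bp_params)
  if (length(rows) == 0L) return(NULL)
  do.call(rbind, rows)
}

#' Feature table for a set of SE items
#'
#' @param events Direction-classified SE events (may be empty).
#' @param internal,external Lists of E-I-E-I-E constructs.
#' @param genome,models,annotation,bp_params As in [extract_se_features()].
#' @return Data frame, one row per item, grouped ISE/DSE/ICE/ECE.
#' @export
se_feature_table <- function(events, internal, external, genome, models,
                             annotation, bp_params = list()) {
  rows <- list()
  if (!is.null(events) && nrow(events) > 0L) {
    for (i in seq_len(nrow(events))) {
      ev <- events[i, ]
      rows[[length(rows) + 1L]] <- extract_se_features(
        ev, genome, models, annotation,
        group = event_group_label("SE", ev$direction), bp_params = bp_params)
    }
  }
  for (cc in internal)
    rows[[length(rows) + 1L]] <- extract_se_features(cc, genome, models,
                                                     annotation, "ICE", bp_params)
  for (cc in external)
    rows[[length(rows) + 1L]] <- extract_se_features(cc, genome, models,
                                                     annotation, "ECE", bp_params)
  if (length(rows) == 0L) return(NULL)
  do.call(rbind, rows)
}
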