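# Control constructs: E-I-E (for retained-intron analysis) and E-I-E-I-E
# (for skipped-exon analysis) chains of annotated exons/introns of a single
# transcript, used as matched background sets.

#' Genomic footprints of a gene's events
#'
#' For each event, the union interval spanning its own E-I-E (RI) or
#' E-I-E-I-E (SE) footprint from the rMATS flank coordinates; for
#' A5SS/A3SS/MXE, the span from the leftmost to the rightmost event
#' coordinate. Internal control candidates must not overlap any footprint.
#'
#' @param events Data frame of (filtered) events for one gene, any kinds.
#' @return An n x 2 matrix of `[start, end)` intervals, one row per event.
#' @export
event_footprints <- function(events) {
  if (is.null(events) || nrow(events) == 0L)
    return(cbind(start = integer(0), end = integer(0)))
  coord_cols <- list(
    SE = c("upstream_es", "upstream_ee", "exon_start", "exon_end",
           "downstream_es", "downstream_ee"),
    RI = c("upstream_es", "upstream_ee", "intron_start", "intron_end",
           "downstream_es", "downstream_ee"),
    A5SS = c("long_exon_start", "long_exon_end", "short_es", "short_ee",
             "flanking_es", "flanking_ee"),
    A3SS = c("long_exon_start", "long_exon_end", "short_es", "short_ee",
             "flanking_es", "flanking_ee"),
    MXE = c("upstream_es", "upstream_ee", "exon1_start", "exon1_end",
            "exon2_start", "exon2_end", "downstream_es", "downstream_ee")
  )
  t(vapply(seq_len(nrow(events)), function(i) {
    cols <- coord_cols[[events$kind[i]]]
    v <- unlist(events[i, cols])
    c(start = min(v), end = max(v))
  }, c(start = 0, end = 0)))
}

# Genomic exon row index for transcript-order exon i.
.t2g_exon <- function(tx, i) {
  n <- nrow(tx$exons)
  if (tx$strand == "+") i else n + 1L - i
}

# Build one construct whose first exon (transcript order) is t-index i.
.make_construct <- function(tx, i, shape, origin, event_id = NA_character_) {
  introns <- tx_introns(tx)
  n_seg_exons <- if (shape == "EIE") 2L else 3L
  roles <- character(0); starts <- integer(0); ends <- integer(0)
  for (k in seq_len(n_seg_exons)) {
    ge <- .t2g_exon(tx, i + k - 1L)
    roles <- c(roles, "exon")
    starts <- c(starts, tx$exons[ge, "start"]); ends <- c(ends, tx$exons[ge, "end"])
    if (k < n_seg_exons) {
      gi <- if (tx$strand == "+") ge else ge - 1L
      roles <- c(roles, "intron")
      starts <- c(starts, introns[gi, "start"]); ends <- c(ends, introns[gi, "end"])
    }
  }
  structure(list(
    shape = shape, origin = origin,
    gene_id = tx$gene_id, transcript_id = tx$transcript_id,
    chrom = tx$chrom, strand = tx$strand,
    event_id = event_id,
    first_exon = i,
    focal_index = if (shape == "EIE") 2L else 3L,
    segments = data.frame(role = roles, start = starts, end = ends,
                          stringsAsFactors = FALSE),
    span = c(start = min(starts), end = max(ends))
  ), class = "sp_construct")
}

#' Enumerate internal control candidates
#'
#' All windows of the requested shape over consecutive exons/introns of the
#' transcript (in transcript 5'->3' order) whose genomic span overlaps no
#' event footprint. May legitimately be empty for transcripts with few exons.
#'
#' @param tx Reference transcript model.
#' @param footprints Matrix from [event_footprints()] for all of the gene's
#'   filtered events.
#' @param shape `"EIE"` or `"EIEIE"`.
#' @param origin Provenance label stored on the constructs.
#' @param event_id Optional event id the candidates are matched to.
#' @return List of construct objects (possibly empty).
#' @export
enumerate_internal_candidates <- function(tx, footprints, shape = c("EIE", "EIEIE"),
                                          origin = "internal",
                                          event_id = NA_character_) {
  shape <- match.arg(shape)
  n <- nrow(tx$exons)
  need <- if (shape == "EIE") 2L else 3L
  if (n < need) return(list())
  out <- list()
  for (i in seq_len(n - need + 1L)) {
    cand <- .make_construct(tx, i, shape, origin, event_id)
    s <- cand$span["start"]; e <- cand$span["end"]
    if (nrow(footprints) > 0L &&
        any(s < footprints[, "end"] & footprints[, "start"] < e)) next
    out[[length(out) + 1L]] <- cand
  }
  out
}

#' Sample one construct uniformly
#'
#' @param candidates List of constructs.
#' @return One construct drawn uniformly with the current RNG state, or
#'   `NULL` when the pool is empty. Identical seed, identical choice.
#' @export
sample_one <- function(candidates) {
  if (length(candidates) == 0L) return(NULL)
  candidates[[sample.int(length(candidates), 1L)]]
}

#' Load a gene-level expression table
#'
#' @param path Two-column tab-separated file with header `gene_id`,
#'   `expression`.
#' @return Data frame with unique `gene_id` and nonnegative `expression`.
#' @export
load_expression_table <- function(path) {
  if (!file.exists(path)) stop("expression table not found: ", path)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (!all(c("gene_id", "expression") %in% names(tab)))
    stop("expression table must have columns gene_id, expression")
  tab$expression <- as.numeric(tab$expression)
  if (anyDuplicated(tab$gene_id)) stop("duplicate gene_id in expression table")
  if (any(is.na(tab$expression)) || any(tab$expression < 0))
    stop("expression values must be nonnegative numbers")
  tab
}

#' Select the external control gene pool
#'
#' Ranks genes by expression (descending; ties broken by gene id for
#' determinism) and keeps the top `n` after dropping mitochondrial genes,
#' genes present in any filtered event table, genes without a qualifying
#' reference transcript, and — for the `EIEIE` shape — genes whose reference
#' transcript has fewer than three exons.
#'
#' @param expr Data frame from [load_expression_table()].
#' @param annotation Annotation from [load_annotation()].
#' @param excluded_gene_ids Character vector: union of gene ids across all
#'   filtered event tables.
#' @param shape `"EIE"` or `"EIEIE"`.
#' @param n Pool size (default 1200).
#' @return Character vector of gene ids, ordered by decreasing expression.
#' @export
select_external_genes <- function(expr, annotation, excluded_gene_ids,
                                  shape = c("EIE", "EIEIE"), n = 1200L) {
  shape <- match.arg(shape)
  min_exons <- if (shape == "EIEIE") 3L else 2L
  ord <- order(-expr$expression, expr$gene_id)
  ranked <- expr$gene_id[ord]
  keep <- vapply(ranked, function(gid) {
    g <- annotation$genes[[gid]]
    if (is.null(g) || g$is_mitochondrial || gid %in% excluded_gene_ids)
      return(FALSE)
    tx <- select_reference_transcript(g)
    !is.null(tx) && nrow(tx$exons) >= min_exons
  }, logical(1))
  pool <- ranked[keep]
  if (length(pool) < n) {
    warning("external pool has only ", length(pool), " genes (requested ", n, ")")
    return(pool)
  }
  pool[seq_len(n)]
}

#' Build external control constructs
#'
#' For each gene's reference transcript, enumerates all windows of the shape
#' (no footprint exclusion; these genes carry no events) and samples one
#' uniformly. Genes yielding no window are skipped.
#'
#' @param gene_ids Pool from [select_external_genes()].
#' @param annotation Annotation object.
#' @param shape `"EIE"` or `"EIEIE"`.
#' @return List of constructs with origin `"external"`.
#' @export
build_external_controls <- function(gene_ids, annotation, shape = c("EIE", "EIEIE")) {
  shape <- match.arg(shape)
  none <- cbind(start = integer(0), end = integer(0))
  out <- list()
  n_skipped <- 0L
  for (gid in gene_ids) {
    tx <- select_reference_transcript(annotation$genes[[gid]])
    cands <- enumerate_internal_candidates(tx, none, shape, origin = "external")
    pick <- sample_one(cands)
    if (is.null(pick)) n_skipped <- n_skipped + 1L else out[[length(out) + 1L]] <- pick
  }
  if (n_skipped > 0L)
    warning(n_skipped, " external gene(s) yielded no ", shape, " window; skipped")
  out
}

#' Build internal control constructs for RI and SE events
#'
#' One construct per event: candidates are enumerated over the event gene's
#' reference transcript, excluding the footprints of ALL of that gene's
#' filtered events (any kind), and one is sampled uniformly. Events whose
#' gene lacks a reference transcript, or with an empty candidate pool, get
#' no construct (counted).
#'
#' @param events Filtered, direction-classified RI and SE events.
#' @param all_events All filtered events of every kind (footprint source).
#' @param annotation Annotation object.
#' @return List with `constructs` (origin `"internal"`, tagged with
#'   `event_id`) and `n_failed`.
#' @export
build_internal_controls <- function(events, all_events, annotation) {
  out <- list()
  n_failed <- 0L
  if (nrow(events) == 0L) return(list(constructs = out, n_failed = 0L))
  fp_by_gene <- lapply(split(all_events, all_events$gene_id), event_footprints)
  for (i in seq_len(nrow(events))) {
    ev <- events[i, ]
    gene <- annotation$genes[[ev$gene_id]]
    tx <- if (is.null(gene)) NULL else select_reference_transcript(gene)
    if (is.null(tx)) { n_failed <- n_failed + 1L; next }
    shape <- if (ev$kind == "RI") "EIE" else "EIEIE"
    cands <- enumerate_internal_candidates(tx, fp_by_gene[[ev$gene_id]], shape,
                                           origin = "internal",
                                           event_id = ev$event_id)
    pick <- sample_one(cands)
    if (is.null(pick)) n_failed <- n_failed + 1L else out[[length(out) + 1L]] <- pick
  }
  list(constructs = out, n_failed = n_failed)
}

#' Serialize constructs to a data frame
#'
#' One row per construct; segment coordinates are comma-joined in transcript
#' order so the table round-trips losslessly through a TSV.
#'
#' @param constructs List of constructs.
#' @return Data frame.
#' @export
constructs_to_table <- function(constructs) {
  if (length(constructs) == 0L) {
    return(data.frame(shape = character(0), origin = character(0),
                      gene_id = character(0), transcript_id = character(0),
                      chrom = character(0), strand = character(0),
                      event_id = character(0), first_exon = integer(0),
                      focal_index = integer(0), seg_roles = character(0),
                      seg_starts = character(0), seg_ends = character(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(constructs, function(cc) {
    data.frame(shape = cc$shape, origin = cc$origin, gene_id = cc$gene_id,
               transcript_id = cc$transcript_id, chrom = cc$chrom,
               strand = cc$strand, event_id = cc$event_id,
               first_exon = cc$first_exon, focal_index = cc$focal_index,
               seg_roles = paste(cc$segments$role, collapse = ","),
               seg_starts = paste(cc$segments$start, collapse = ","),
               seg_ends = paste(cc$segments$end, collapse = ","),
               stringsAsFactors = FALSE)
  }))
}

#' Rebuild constructs from a serialized table
#' @param tab Data frame from [constructs_to_table()].
#' @return List of constructs.
#' @export
table_to_constructs <- function(tab) {
  lapply(seq_len(nrow(tab)), function(i) {
    starts <- as.integer(strsplit(tab$seg_starts[i], ",")[[1]])
    ends <- as.integer(strsplit(tab$seg_ends[i], ",")[[1]])
    structure(list(
      shape = tab$shape[i], origin = tab$origin[i],
      gene_id = tab$gene_id[i], transcript_id = tab$transcript_id[i],
      chrom = tab$chrom[i], strand = tab$strand[i],
      event_id = tab$event_id[i], first_exon = tab$first_exon[i],
      focal_index = tab$focal_index[i],
      segments = data.frame(role = strsplit(tab$seg_roles[i], ",")[[1]],
                            start = starts, end = ends,
                            stringsAsFactors = FALSE),
      span = c(start = min(starts), end = max(ends))
    ), class = "sp_construct")
  })
}
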