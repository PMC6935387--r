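EVENT_KINDS <- c("SE", "RI", "A5SS", "A3SS", "MXE")

# rMATS column dialect per event kind: coordinate columns are already
# 0-based starts ("...Start_0base"/"...ES") and exclusive ends ("...End"/"...EE").
# `std` gives the internal column each maps onto.
.rmats_coord_map <- function(kind) {
  switch(kind,
    SE = c(exonStart_0base = "exon_start", exonEnd = "exon_end",
           upstreamES = "upstream_es", upstreamEE = "upstream_ee",
           downstreamES = "downstream_es", downstreamEE = "downstream_ee"),
    RI = c(riExonStart_0base = "ri_exon_start", riExonEnd = "ri_exon_end",
           upstreamES = "upstream_es", upstreamEE = "upstream_ee",
           downstreamES = "downstream_es", downstreamEE = "downstream_ee"),
    A5SS = ,
    A3SS = c(longExonStart_0base = "long_exon_start", longExonEnd = "long_exon_end",
             shortES = "short_es", shortEE = "short_ee",
             flankingES = "flanking_es", flankingEE = "flanking_ee"),
    MXE = c(`X1stExonStart_0base` = "exon1_start", `X1stExonEnd` = "exon1_end",
            `X2ndExonStart_0base` = "exon2_start", `X2ndExonEnd` = "exon2_end",
            upstreamES = "upstream_es", upstreamEE = "upstream_ee",
            downstreamES = "downstream_es", downstreamEE = "downstream_ee"),
    stop("unknown rMATS event kind: ", kind)
  )
}

#' Parse an rMATS-style event table
#'
#' Reads one of the five rMATS event tables (`SE`, `RI`, `A5SS`, `A3SS`,
#' `MXE`; JC or JCEC dialect) into a standardized data frame. rMATS
#' `...Start_0base`/`...ES` columns are taken as 0-based starts and
#' `...End`/`...EE` as exclusive ends, so coordinates are stored unchanged
#' as 0-based half-open intervals. Rows whose `PValue` or `FDR` is not
#' numeric (e.g. `"NA"`) are dropped with a warning.
#'
#' @param path Path to the tab-separated table (header row required).
#' @param kind One of `"SE"`, `"RI"`, `"A5SS"`, `"A3SS"`, `"MXE"`.
#' @return A data frame with columns `event_id`, `kind`, `gene_id`, `chrom`,
#'   `strand`, kind-specific coordinate columns, `p_value`, `fdr`,
#'   `inc_level_diff`. For `RI`, the retained intron `[intron_start,
#'   intron_end)` is derived as the gap between the flanking exons.
#' @export
parse_rmats_table <- function(path, kind) {
  kind <- match.arg(kind, EVENT_KINDS)
  if (!file.exists(path)) stop("rMATS table not found: ", path)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = TRUE,
                           colClasses = "character")
  cmap <- .rmats_coord_map(kind)
  # rMATS writes "1stExonStart_0base" which read.delim mangles to X1st...
  required <- c("GeneID", "chr", "strand", names(cmap),
                "PValue", "FDR", "IncLevelDifference")
  missing <- setdiff(required, names(tab))
  if (length(missing) > 0L)
    stop("rMATS ", kind, " table missing required column(s): ",
         paste(sub("^X", "", missing), collapse = ", "))

  p <- suppressWarnings(as.numeric(tab$PValue))
  q <- suppressWarnings(as.numeric(tab$FDR))
  bad <- is.na(p) | is.na(q)
  if (any(bad)) {
    warning(sum(bad), " ", kind, " row(s) with non-numeric PValue/FDR dropped")
    tab <- tab[!bad, , drop = FALSE]
    p <- p[!bad]; q <- q[!bad]
  }

  id <- if ("ID" %in% names(tab)) tab$ID else as.character(seq_len(nrow(tab)))
  out <- data.frame(
    event_id = paste0(kind, "_", id),
    kind = rep(kind, nrow(tab)),
    gene_id = gsub('"', "", tab$GeneID),
    chrom = tab$chr,
    strand = tab$strand,
    stringsAsFactors = FALSE
  )
  for (col in names(cmap)) out[[cmap[[col]]]] <- as.integer(tab[[col]])
  if (kind == "RI") {
    # upstream/downstream flanks are transcript-relative in rMATS output;
    # the retained intron is the genomic gap between them
    plus <- out$strand == "+"
    out$intron_start <- ifelse(plus, out$upstream_ee, out$downstream_ee)
    out$intron_end <- ifelse(plus, out$downstream_es, out$upstream_es)
  }
  out$p_value <- p
  out$fdr <- q
  out$inc_level_diff <- suppressWarnings(as.numeric(tab$IncLevelDifference))
  out
}

#' Filter events on significance
#'
#' Keeps events with `p_value < p_max` AND `fdr < fdr_max` (both strict).
#'
#' @param events Data frame from [parse_rmats_table()].
#' @param p_max,fdr_max Thresholds, default 0.05 each.
#' @return The retained subset, same columns.
#' @export
filter_events <- function(events, p_max = 0.05, fdr_max = 0.05) {
  if (nrow(events) == 0L) return(events)
  events[events$p_value < p_max & events$fdr < fdr_max, , drop = FALSE]
}

#' Classify event direction in the mutant
#'
#' With rMATS group 1 = wild type, `IncLevelDifference = IncLevel1 -
#' IncLevel2`, so a negative difference means inclusion of the focal form is
#' higher in the mutant: increased retention for RI, decreased skipping
#' (i.e. higher exon inclusion) for SE. The mapping inverts when group 1 is
#' the mutant. A zero difference is ambiguous after the significance filter
#' and is a hard error.
#'
#' @param events Filtered event data frame.
#' @param g1_is_wildtype Logical flag; mandatory (no default) because the
#'   sign convention silently inverts every direction-stratified result.
#' @return `events` with a `direction` column added, one of
#'   `"increased_in_mutant"` / `"decreased_in_mutant"` (inclusion of the
#'   focal form: intron retention for RI, exon inclusion for SE).
#' @export
classify_direction <- function(events, g1_is_wildtype) {
  stopifnot(is.logical(g1_is_wildtype), length(g1_is_wildtype) == 1L)
  if (nrow(events) > 0L && any(events$inc_level_diff == 0))
    stop("IncLevelDifference of 0 is ambiguous; cannot classify direction")
  d <- events$inc_level_diff
  if (!g1_is_wildtype) d <- -d
  events$direction <- ifelse(d < 0, "increased_in_mutant", "decreased_in_mutant")
  events
}

# Fig 6/7-style group label for an event.
event_group_label <- function(kind, direction) {
  if (kind == "RI") {
    ifelse(direction == "increased_in_mutant", "IRI", "DRI")
  } else if (kind == "SE") {
    # increased inclusion = decreased skipping
    ifelse(direction == "increased_in_mutant", "DSE", "ISE")
  } else stop("group labels defined for RI and SE only")
}

#' Summarize genes with multiple kinds of altered splicing
#'
#' Venn-style tally of which event kinds co-occur per gene across the five
#' filtered tables.
#'
#' @param event_list Named list of filtered event data frames (names are
#'   kinds; any subset of the five).
#' @return A list with `gene_kinds` (data frame: `gene_id`, `kinds`
#'   comma-collapsed in fixed SE/RI/A5SS/A3SS/MXE order, `n_kinds`),
#'   `n_multi_kind` (genes with >= 2 kinds) and `combo_counts` (named
#'   integer vector keyed by the kind combination).
#' @export
multi_event_summary <- function(event_list) {
  pairs <- do.call(rbind, lapply(names(event_list), function(k) {
    ev <- event_list[[k]]
    if (is.null(ev) || nrow(ev) == 0L) return(NULL)
    data.frame(gene_id = unique(ev$gene_id), kind = k, stringsAsFactors = FALSE)
  }))
  if (is.null(pairs) || nrow(pairs) == 0L) {
    return(list(gene_kinds = data.frame(gene_id = character(0),
                                        kinds = character(0),
                                        n_kinds = integer(0)),
                n_multi_kind = 0L,
                combo_counts = setNames(integer(0), character(0))))
  }
  sp <- split(pairs$kind, pairs$gene_id)
  kinds <- vapply(sp, function(k)
    paste(intersect(EVENT_KINDS, unique(k)), collapse = ","), character(1))
  gk <- data.frame(gene_id = names(sp), kinds = kinds,
                   n_kinds = vapply(sp, function(k) length(unique(k)), integer(1)),
                   stringsAsFactors = FALSE, row.names = NULL)
  combo <- table(gk$kinds)
  list(gene_kinds = gk,
       n_multi_kind = sum(gk$n_kinds >= 2L),
       combo_counts = setNames(as.integer(combo), names(combo)))
}
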