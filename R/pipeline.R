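# End-to-end orchestration: load inputs, filter events, build controls,
# train scorers, extract features, compare, and write report tables.

#' Pipeline run configuration
#'
#' @param genome,gtf,expression Paths to the genome FASTA, GTF annotation
#'   and gene expression TSV.
#' @param rmats_dir Directory holding the five `<KIND>.MATS.<mode>.txt`
#'   tables.
#' @param outdir Output directory.
#' @param g1_is_wildtype Mandatory logical: was rMATS group 1 the wild-type
#'   sample set? There is no safe default; the sign convention inverts
#'   every direction-stratified result.
#' @param seed Mandatory integer seed for all sampling.
#' @param counting_mode `"JCEC"` (default) or `"JC"`.
#' @param p_max,fdr_max Event significance thresholds, default 0.05 each.
#' @param alpha Significance level for comparisons, default 0.05.
#' @param adjust_method `"bh"` (default) or `"bonferroni"`.
#' @param external_pool_size External control pool size, default 1200
#'   (override downwards for small fixtures).
#' @param bp List of [find_branch_point()] arguments.
#' @param kmer List of [kmer_enrichment()] arguments (`k_min`, `k_max`,
#'   `n_perm`, `min_fg_frac`).
#' @param run_motifs Run the k-mer enrichment stage (default TRUE).
#' @param scorer_mode `"trained"` (default) or `"external_tables"`.
#' @param donor_table,acceptor_table Score-table paths for
#'   `scorer_mode = "external_tables"`.
#' @param mito_chroms Mitochondrial chromosome names.
#' @return Object of class `sp_run_config`.
#' @export
run_config <- function(genome, gtf, rmats_dir, expression, outdir,
                       g1_is_wildtype, seed,
                       counting_mode = c("JCEC", "JC"),
                       p_max = 0.05, fdr_max = 0.05,
                       alpha = 0.05, adjust_method = c("bh", "bonferroni"),
                       external_pool_size = 1200L,
                       bp = list(search_min = 15L, search_max = 500L,
                                 ppt_window = 25L, ppt_weight = 2.0),
                       kmer = list(k_min = 5L, k_max = 6L, n_perm = 500L,
                                   min_fg_frac = 0.2),
                       run_motifs = TRUE,
                       scorer_mode = c("trained", "external_tables"),
                       donor_table = NULL, acceptor_table = NULL,
                       mito_chroms = DEFAULT_MITO_CHROMS) {
  if (missing(g1_is_wildtype)) stop("g1_is_wildtype must be set explicitly")
  if (missing(seed)) stop("seed must be set explicitly")
  stopifnot(alpha > 0, alpha < 1)
  structure(list(
    genome = genome, gtf = gtf, rmats_dir = rmats_dir,
    expression = expression, outdir = outdir,
    g1_is_wildtype = isTRUE(g1_is_wildtype), seed = as.integer(seed),
    counting_mode = match.arg(counting_mode),
    p_max = p_max, fdr_max = fdr_max, alpha = alpha,
    adjust_method = match.arg(adjust_method),
    external_pool_size = as.integer(external_pool_size),
    bp = bp, kmer = kmer, run_motifs = isTRUE(run_motifs),
    scorer_mode = match.arg(scorer_mode),
    donor_table = donor_table, acceptor_table = acceptor_table,
    mito_chroms = mito_chroms
  ), class = "sp_run_config")
}

#' Pipeline configuration for a synthetic dataset directory
#'
#' Convenience wrapper around [run_config()] pointing every input path at a
#' [generate_dataset()] output directory. The synthetic generator encodes
#' group 1 as wild type.
#'
#' @param dir Dataset directory.
#' @param outdir Output directory.
#' @param seed Seed.
#' @param ... Further [run_config()] overrides.
#' @return `sp_run_config`.
#' @export
run_config_for_dataset <- function(dir, outdir, seed, ...) {
  run_config(genome = file.path(dir, "genome.fa"),
             gtf = file.path(dir, "annotation.gtf"),
             rmats_dir = dir,
             expression = file.path(dir, "expression.tsv"),
             outdir = outdir, g1_is_wildtype = TRUE, seed = seed, ...)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", name, "': ", conditionMessage(e), call. = FALSE))
}

#' Run the full characterization pipeline
#'
#' Stages, in order: load genome/annotation; parse and filter the five
#' event tables; classify direction; build internal and external controls;
#' train donor/acceptor scorers; extract RI and SE feature tables; run
#' group comparisons and qualitative summaries; run discriminative k-mer
#' enrichment; write all tables plus a JSON run report. Identical inputs,
#' configuration and seed give byte-identical outputs.
#'
#' @param config From [run_config()].
#' @return Invisibly, the run report (also written to `report.json`),
#'   together with the in-memory tables in attribute-free list elements
#'   `ri_features`, `se_features`, `comparisons`, `summary`, `motifs`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "sp_run_config"))
  set.seed(config$seed)
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)

  genome <- .stage("genome", load_genome(config$genome))
  annotation <- .stage("annotation",
                       load_annotation(config$gtf, config$mito_chroms))

  parsed <- list(); filtered <- list()
  .stage("events", {
    for (kind in EVENT_KINDS) {
      path <- file.path(config$rmats_dir,
                        paste0(kind, ".MATS.", config$counting_mode, ".txt"))
      if (!file.exists(path)) stop("missing rMATS table: ", path)
      ev <- parse_rmats_table(path, kind)
      parsed[[kind]] <- ev
      fe <- filter_events(ev, config$p_max, config$fdr_max)
      known <- fe$gene_id %in% names(annotation$genes)
      if (any(!known)) {
        warning(sum(!known), " filtered ", kind,
                " event(s) in genes absent from the annotation dropped")
        fe <- fe[known, , drop = FALSE]
      }
      filtered[[kind]] <- classify_direction(fe, config$g1_is_wildtype)
    }
  })
  multi <- multi_event_summary(filtered)
  all_filtered <- do.call(rbind, lapply(filtered, function(x)
    x[, c("event_id", "kind", "gene_id", "chrom", "strand",
          "p_value", "fdr", "inc_level_diff", "direction")]))

  expr <- .stage("expression", load_expression_table(config$expression))

  # controls (fixed sampling order for reproducibility)
  internal_ri <- .stage("internal_controls",
    build_internal_controls(filtered$RI, .all_coord_events(filtered), annotation))
  internal_se <- .stage("internal_controls",
    build_internal_controls(filtered$SE, .all_coord_events(filtered), annotation))
  excluded <- unique(unlist(lapply(filtered, function(x) x$gene_id)))
  pool_eie <- .stage("external_controls",
    select_external_genes(expr, annotation, excluded, "EIE",
                          config$external_pool_size))
  pool_eieie <- .stage("external_controls",
    select_external_genes(expr, annotation, excluded, "EIEIE",
                          config$external_pool_size))
  external_ri <- .stage("external_controls",
                        build_external_controls(pool_eie, annotation, "EIE"))
  external_se <- .stage("external_controls",
                        build_external_controls(pool_eieie, annotation, "EIEIE"))

  models <- .stage("splice_models", {
    if (config$scorer_mode == "external_tables") {
      list(donor = load_external_score_tables(config$donor_table),
           acceptor = load_external_score_tables(config$acceptor_table),
           background = NULL, training = NULL)
    } else {
      bg <- genome_background(genome)
      dw <- collect_training_sites(annotation, genome, "donor")
      aw <- collect_training_sites(annotation, genome, "acceptor")
      list(donor = train_splice_model(dw, "donor", background = bg),
           acceptor = train_splice_model(aw, "acceptor", background = bg),
           background = bg,
           training = list(n_donor = length(dw), n_acceptor = length(aw)))
    }
  })

  ri_features <- .stage("features",
    ri_feature_table(filtered$RI, internal_ri$constructs, external_ri,
                     genome, models, annotation, config$bp))
  se_features <- .stage("features",
    se_feature_table(filtered$SE, internal_se$constructs, external_se,
                     genome, models, annotation, config$bp))

  ri_cols <- c("donor_score", "acceptor_score", "focal_length", "focal_gc",
               "upstream_exon_len", "downstream_exon_len", "bp_offset")
  se_cols <- c("donor_score", "acceptor_score", "upstream_donor_score",
               "downstream_acceptor_score", "focal_length", "focal_gc",
               "upstream_intron_len", "downstream_intron_len",
               "upstream_intron_gc", "downstream_intron_gc",
               "bp_offset_upstream", "bp_offset_downstream")
  comparisons <- NULL; summaries <- NULL
  .stage("comparisons", {
    res <- list()
    if (!is.null(ri_features) && any(ri_features$group %in% c("IRI", "DRI")))
      res$RI <- summarize_feature_table(ri_features, ri_cols,
                                        intersect(c("IRI", "DRI"), unique(ri_features$group)),
                                        "ICI", "ECI", config$alpha,
                                        config$adjust_method)
    if (!is.null(se_features) && any(se_features$group %in% c("ISE", "DSE")))
      res$SE <- summarize_feature_table(se_features, se_cols,
                                        intersect(c("ISE", "DSE"), unique(se_features$group)),
                                        "ICE", "ECE", config$alpha,
                                        config$adjust_method)
    comparisons <- do.call(rbind, c(lapply(names(res), function(k)
      cbind(data.frame(table = k, stringsAsFactors = FALSE),
            res[[k]]$comparisons)), list(make.row.names = FALSE)))
    summaries <- do.call(rbind, c(lapply(names(res), function(k)
      cbind(data.frame(table = k, stringsAsFactors = FALSE),
            res[[k]]$summary)), list(make.row.names = FALSE)))
  })

  motifs <- NULL
  if (config$run_motifs) motifs <- .stage("motifs",
    .run_motifs(filtered, internal_ri$constructs, internal_se$constructs,
                external_ri, external_se, genome, config))

  # --- outputs -------------------------------------------------------------
  out <- function(x) file.path(config$outdir, x)
  wt <- function(df, fn) {
    if (is.null(df)) df <- data.frame()
    utils::write.table(df, out(fn), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  wt(ri_features, "ri_features.tsv")
  wt(se_features, "se_features.tsv")
  wt(comparisons, "comparisons.tsv")
  wt(summaries, "summary.tsv")
  wt(motifs, "motifs.tsv")
  wt(constructs_to_table(c(internal_ri$constructs, internal_se$constructs,
                           external_ri, external_se)), "controls.tsv")
  wt(all_filtered, "filtered_events.tsv")
  wt(multi$gene_kinds, "multi_event_genes.tsv")

  report <- list(
    package = "spliceprops",
    config = list(counting_mode = config$counting_mode,
                  g1_is_wildtype = config$g1_is_wildtype,
                  p_max = config$p_max, fdr_max = config$fdr_max,
                  alpha = config$alpha, adjust_method = config$adjust_method,
                  external_pool_size = config$external_pool_size,
                  seed = config$seed, scorer_mode = config$scorer_mode),
    input_md5 = as.list(setNames(
      unname(tools::md5sum(c(config$genome, config$gtf, config$expression))),
      basename(c(config$genome, config$gtf, config$expression)))),
    counts = list(
      parsed = lapply(parsed, nrow),
      filtered = lapply(filtered, nrow),
      genes_with_events = length(unique(all_filtered$gene_id)),
      multi_kind_genes = multi$n_multi_kind,
      internal_ri = length(internal_ri$constructs),
      internal_ri_failed = internal_ri$n_failed,
      internal_se = length(internal_se$constructs),
      internal_se_failed = internal_se$n_failed,
      external_pool_eie = length(pool_eie),
      external_pool_eieie = length(pool_eieie),
      external_ri = length(external_ri),
      external_se = length(external_se),
      ri_items_n_flagged = if (is.null(ri_features)) 0L else sum(ri_features$n_in_window),
      se_items_n_flagged = if (is.null(se_features)) 0L else sum(se_features$n_in_window),
      training = models$training
    ),
    outputs = c("ri_features.tsv", "se_features.tsv", "comparisons.tsv",
                "summary.tsv", "motifs.tsv", "controls.tsv",
                "filtered_events.tsv", "multi_event_genes.tsv")
  )
  jsonlite::write_json(report, out("report.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)

  invisible(c(report, list(ri_features = ri_features, se_features = se_features,
                           comparisons = comparisons, summary = summaries,
                           motifs = motifs)))
}

# Events of all kinds in one frame (union of coordinate columns, NA where a
# kind lacks one), for per-gene footprint computation.
.all_coord_events <- function(filtered) {
  cols <- c("event_id", "kind", "gene_id", "chrom", "strand",
            "exon_start", "exon_end", "upstream_es", "upstream_ee",
            "downstream_es", "downstream_ee", "intron_start", "intron_end",
            "ri_exon_start", "ri_exon_end", "long_exon_start", "long_exon_end",
            "short_es", "short_ee", "flanking_es", "flanking_ee",
            "exon1_start", "exon1_end", "exon2_start", "exon2_end")
  do.call(rbind, lapply(unname(filtered), function(x) {
    for (cn in setdiff(cols, names(x))) x[[cn]] <- NA_integer_
    x[, cols, drop = FALSE]
  }))
}

.construct_span_seq <- function(cc, genome) {
  get_sequence(genome, cc$chrom, cc$span[["start"]], cc$span[["end"]], cc$strand)
}

.event_span_seq <- function(ev, genome) {
  fp <- event_footprints(ev)
  get_sequence(genome, ev$chrom, fp[1, "start"], fp[1, "end"], ev$strand)
}

# Discriminative k-mer enrichment of each event group against each control
# origin, RI (E-I-E spans) and SE (E-I-E-I-E spans) separately.
.run_motifs <- function(filtered, internal_ri, internal_se, external_ri,
                        external_se, genome, config) {
  km <- config$kmer
  one <- function(fg, bg, label) {
    if (length(fg) < 2L || length(bg) < 2L) return(NULL)
    hits <- kmer_enrichment(fg, bg, k_min = km$k_min, k_max = km$k_max,
                            n_perm = km$n_perm, min_fg_frac = km$min_fg_frac,
                            alpha = config$alpha)
    if (nrow(hits) == 0L) return(NULL)
    cbind(data.frame(comparison = label, stringsAsFactors = FALSE), hits)
  }
  group_seqs <- function(events, kind) {
    if (is.null(events) || nrow(events) == 0L) return(list())
    sp <- split(seq_len(nrow(events)), event_group_label(kind, events$direction))
    lapply(sp, function(idx) vapply(idx, function(i)
      .event_span_seq(events[i, ], genome), character(1)))
  }
  ctrl_seqs <- function(ccs) vapply(ccs, .construct_span_seq, character(1),
                                    genome = genome)
  res <- list()
  ri_groups <- group_seqs(filtered$RI, "RI")
  for (g in names(ri_groups)) {
    res[[length(res) + 1L]] <- one(ri_groups[[g]], ctrl_seqs(internal_ri),
                                   paste0(g, "_vs_ICI"))
    res[[length(res) + 1L]] <- one(ri_groups[[g]], ctrl_seqs(external_ri),
                                   paste0(g, "_vs_ECI"))
  }
  se_groups <- group_seqs(filtered$SE, "SE")
  for (g in names(se_groups)) {
    res[[length(res) + 1L]] <- one(se_groups[[g]], ctrl_seqs(internal_se),
                                   paste0(g, "_vs_ICE"))
    res[[length(res) + 1L]] <- one(se_groups[[g]], ctrl_seqs(external_se),
                                   paste0(g, "_vs_ECE"))
  }
  res <- Filter(Negate(is.null), res)
  if (length(res) == 0L) return(NULL)
  do.call(rbind, res)
}
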