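# Group comparisons of event vs control feature distributions, qualitative
# summary tables, threshold fractions, and discriminative k-mer enrichment.

#' Compare two groups of measurements
#'
#' Welch's unpaired two-sided t test. A Kolmogorov-Smirnov normality flag
#' (against a normal with the sample's moments) is attached per group for
#' information; the t test is run regardless.
#'
#' @param values_a,values_b Numeric vectors, each with at least 2 finite
#'   values. NAs are dropped.
#' @param alpha Significance level used for the verdict, default 0.05.
#' @return One-row data frame: group sizes, means, t statistic, `p_value`,
#'   `p_adjusted` (initialized to `p_value`; see [adjust_pvalues()]),
#'   KS normality p per group, and a `verdict`
#'   (`"higher"`/`"lower"`/`"no_significant_difference"`, stated for group
#'   a relative to group b).
#' @export
compare_groups <- function(values_a, values_b, alpha = 0.05) {
  a <- values_a[is.finite(values_a)]
  b <- values_b[is.finite(values_b)]
  if (length(a) < 2L || length(b) < 2L)
    stop("compare_groups needs at least 2 finite values per group")
  tt <- stats::t.test(a, b, var.equal = FALSE)
  ks_p <- function(x) {
    if (stats::sd(x) == 0) return(NA_real_)
    suppressWarnings(stats::ks.test(x, "pnorm", mean(x), stats::sd(x))$p.value)
  }
  p <- tt$p.value
  if (is.na(p)) p <- 1  # identical constant groups
  res <- data.frame(
    n_a = length(a), n_b = length(b),
    mean_a = mean(a), mean_b = mean(b),
    statistic = unname(tt$statistic),
    p_value = p, p_adjusted = p,
    ks_normal_p_a = ks_p(a), ks_normal_p_b = ks_p(b),
    stringsAsFactors = FALSE
  )
  res$verdict <- .verdict(res$mean_a, res$mean_b, res$p_adjusted, alpha)
  res
}

.verdict <- function(mean_a, mean_b, p_adj, alpha) {
  ifelse(p_adj >= alpha | mean_a == mean_b, "no_significant_difference",
         ifelse(mean_a > mean_b, "higher", "lower"))
}

#' Adjust p-values across a comparison table
#'
#' Bonferroni (`min(1, m * p)`) or Benjamini-Hochberg step-up; verdicts are
#' recomputed against `alpha` on the adjusted values.
#'
#' @param results Data frame of [compare_groups()] rows.
#' @param method `"bonferroni"` or `"bh"`.
#' @param alpha Significance level, default 0.05.
#' @return `results` with `p_adjusted` and `verdict` updated.
#' @export
adjust_pvalues <- function(results, method = c("bh", "bonferroni"), alpha = 0.05) {
  method <- match.arg(method)
  if (nrow(results) == 0L) stop("no results to adjust")
  results$p_adjusted <- stats::p.adjust(results$p_value,
                                        method = if (method == "bh") "BH" else "bonferroni")
  results$verdict <- .verdict(results$mean_a, results$mean_b,
                              results$p_adjusted, alpha)
  results
}

#' Fraction of values strictly below a threshold
#'
#' @param values Nonempty numeric vector (NAs dropped).
#' @param threshold Cutoff; strict inequality.
#' @return `count(v < threshold) / n`.
#' @export
fraction_below <- function(values, threshold) {
  v <- values[!is.na(values)]
  if (length(v) == 0L) stop("fraction_below needs at least one value")
  mean(v < threshold)
}

#' Qualitative summary of a feature table
#'
#' For each feature and each event group, compares the event group against
#' the internal and external control groups separately, adjusts p-values
#' across the whole table, and emits a verdict phrase composed from which
#' control sets differ and in which direction (e.g. "Lower than internal
#' and external controls", "No significant difference"). For RI groups an
#' in-frame stop-codon percentage row is included.
#'
#' @param features Feature data frame from [ri_feature_table()] or
#'   [se_feature_table()].
#' @param feature_cols Feature columns to compare.
#' @param event_groups Event group labels present (e.g. `c("IRI", "DRI")`).
#' @param internal_group,external_group Control group labels.
#' @param alpha Significance level.
#' @param method Adjustment method, `"bh"` (default) or `"bonferroni"`.
#' @return List with `comparisons` (all pairwise rows, adjusted) and
#'   `summary` (feature x event-group verdict phrases).
#' @export
summarize_feature_table <- function(features, feature_cols, event_groups,
                                    internal_group, external_group,
                                    alpha = 0.05, method = c("bh", "bonferroni")) {
  method <- match.arg(method)
  comps <- list()
  for (feat in feature_cols) {
    for (eg in event_groups) {
      va <- features[[feat]][features$group == eg]
      for (ctrl in c(internal_group, external_group)) {
        vb <- features[[feat]][features$group == ctrl]
        row <- if (sum(is.finite(va)) < 2L || sum(is.finite(vb)) < 2L) {
          data.frame(n_a = sum(is.finite(va)), n_b = sum(is.finite(vb)),
                     mean_a = NA_real_, mean_b = NA_real_, statistic = NA_real_,
                     p_value = NA_real_, p_adjusted = NA_real_,
                     ks_normal_p_a = NA_real_, ks_normal_p_b = NA_real_,
                     verdict = "not_computed", stringsAsFactors = FALSE)
        } else {
          compare_groups(va, vb, alpha)
        }
        row <- cbind(data.frame(feature = feat, group_a = eg, group_b = ctrl,
                                stringsAsFactors = FALSE), row)
        comps[[length(comps) + 1L]] <- row
      }
    }
  }
  comparisons <- do.call(rbind, comps)
  computed <- !is.na(comparisons$p_value)
  if (any(computed)) {
    adj <- adjust_pvalues(comparisons[computed, , drop = FALSE], method, alpha)
    comparisons$p_adjusted[computed] <- adj$p_adjusted
    comparisons$verdict[computed] <- adj$verdict
  }

  cells <- list()
  for (feat in feature_cols) {
    for (eg in event_groups) {
      vi <- comparisons$verdict[comparisons$feature == feat &
                                  comparisons$group_a == eg &
                                  comparisons$group_b == internal_group]
      ve <- comparisons$verdict[comparisons$feature == feat &
                                  comparisons$group_a == eg &
                                  comparisons$group_b == external_group]
      cells[[length(cells) + 1L]] <- data.frame(
        feature = feat, group = eg,
        phrase = .verdict_phrase(vi, ve), stringsAsFactors = FALSE)
    }
  }
  summary <- do.call(rbind, cells)

  if ("ri_consequence" %in% names(features)) {
    for (eg in event_groups) {
      cons <- features$ri_consequence[features$group == eg]
      cons <- cons[cons != "frame_unavailable"]
      pct <- if (length(cons) == 0L) NA_real_ else
        round(100 * mean(cons == "in_frame_stop"))
      summary <- rbind(summary, data.frame(
        feature = "pct_in_frame_stop", group = eg,
        phrase = if (is.na(pct)) "not_computed" else paste0(pct, "%"),
        stringsAsFactors = FALSE))
    }
  }
  list(comparisons = comparisons, summary = summary)
}

.verdict_phrase <- function(v_int, v_ext) {
  dir <- function(v) if (length(v) == 1L && v %in% c("higher", "lower")) v else NA_character_
  di <- dir(v_int); de <- dir(v_ext)
  if (is.na(di) && is.na(de)) return("No significant difference")
  if (!is.na(di) && !is.na(de) && di == de)
    return(paste0(toupper(substr(di, 1, 1)), substr(di, 2, 10),
                  " than internal and external controls"))
  parts <- character(0)
  if (!is.na(di)) parts <- c(parts, paste0(toupper(substr(di, 1, 1)),
                                           substr(di, 2, 10), " than internal controls"))
  if (!is.na(de)) parts <- c(parts, paste0(toupper(substr(de, 1, 1)),
                                           substr(de, 2, 10), " than external controls"))
  paste(parts, collapse = "; ")
}

#' Discriminative k-mer enrichment with a permutation null
#'
#' For each k in `[k_min, k_max]`, every k-mer present in at least
#' `min_fg_frac` of foreground sequences is tested with the statistic
#' fg presence fraction minus bg presence fraction (presence/absence per
#' sequence). The null permutes group labels `n_perm` times;
#' `p_perm = (1 + #{perm >= observed}) / (1 + n_perm)`. P-values are
#' BH-adjusted across all tested k-mers.
#'
#' @param fg,bg Nonempty character vectors of A/C/G/T sequences.
#' @param k_min,k_max K-mer length range, defaults 5 and 8.
#' @param n_perm Number of label permutations, default 1000.
#' @param min_fg_frac Minimum foreground presence fraction to test a k-mer,
#'   default 0.2.
#' @param alpha Hit threshold on adjusted p, default 0.05.
#' @return Data frame of hits (`p_adjusted < alpha`) sorted by decreasing
#'   enrichment, columns `kmer`, `k`, `fg_freq`, `bg_freq`, `enrichment`,
#'   `p_perm`, `p_adjusted`. The full tested table is attached as attribute
#'   `"all_tested"`.
#' @export
kmer_enrichment <- function(fg, bg, k_min = 5L, k_max = 8L, n_perm = 1000L,
                            min_fg_frac = 0.2, alpha = 0.05) {
  if (length(fg) == 0L || length(bg) == 0L)
    stop("foreground and background must be nonempty")
  if (k_min < 1L || k_max < k_min) stop("invalid k range")
  all_seq <- c(fg, bg)
  n_fg <- length(fg); n_all <- length(all_seq)

  pres_list <- list()
  for (k in k_min:k_max) {
    usable <- nchar(all_seq) >= k
    if (!any(usable[seq_len(n_fg)])) next
    if (any(!usable))
      warning(sum(!usable), " sequence(s) shorter than k=", k, " skipped for that k")
    freq <- Biostrings::oligonucleotideFrequency(
      Biostrings::DNAStringSet(ifelse(usable, all_seq, strrep("N", k))), width = k)
    pres <- freq > 0
    cand <- colMeans(pres[seq_len(n_fg), , drop = FALSE]) >= min_fg_frac
    if (!any(cand)) next
    pm <- pres[, cand, drop = FALSE]
    colnames(pm) <- colnames(pres)[cand]
    pres_list[[as.character(k)]] <- pm
  }
  if (length(pres_list) == 0L) {
    if (max(nchar(fg)) < k_min) stop("all sequences shorter than k_min")
    return(.empty_motif_hits())
  }
  P <- do.call(cbind, pres_list)
  storage.mode(P) <- "double"
  obs <- colMeans(P[seq_len(n_fg), , drop = FALSE]) -
    colMeans(P[-seq_len(n_fg), , drop = FALSE])

  # permutation statistics via one matrix product per block of k-mers
  Z <- matrix(0, n_all, n_perm)
  for (j in seq_len(n_perm)) Z[sample.int(n_all, n_fg), j] <- 1
  scale_fg <- 1 / n_fg
  scale_bg <- 1 / (n_all - n_fg)
  ge_count <- numeric(ncol(P))
  block <- 4096L
  for (s in seq(1L, ncol(P), by = block)) {
    idx <- s:min(ncol(P), s + block - 1L)
    fg_sum <- crossprod(P[, idx, drop = FALSE], Z)      # kmers x perms
    tot <- colSums(P[, idx, drop = FALSE])
    perm_stat <- fg_sum * scale_fg - (tot - fg_sum) * scale_bg
    ge_count[idx] <- rowSums(perm_stat >= obs[idx] - 1e-12)
  }
  p_perm <- (1 + ge_count) / (1 + n_perm)

  fg_freq <- colMeans(P[seq_len(n_fg), , drop = FALSE])
  bg_freq <- colMeans(P[-seq_len(n_fg), , drop = FALSE])
  res <- data.frame(
    kmer = colnames(P), k = nchar(colnames(P)),
    fg_freq = fg_freq, bg_freq = bg_freq,
    enrichment = ifelse(bg_freq > 0, fg_freq / bg_freq, Inf),
    p_perm = p_perm,
    p_adjusted = stats::p.adjust(p_perm, method = "BH"),
    stringsAsFactors = FALSE, row.names = NULL
  )
  hits <- res[res$p_adjusted < alpha, , drop = FALSE]
  hits <- hits[order(-hits$enrichment, hits$p_adjusted, hits$kmer), , drop = FALSE]
  rownames(hits) <- NULL
  attr(hits, "all_tested") <- res
  hits
}

.empty_motif_hits <- function() {
  h <- data.frame(kmer = character(0), k = integer(0), fg_freq = numeric(0),
                  bg_freq = numeric(0), enrichment = numeric(0),
                  p_perm = numeric(0), p_adjusted = numeric(0),
                  stringsAsFactors = FALSE)
  attr(h, "all_tested") <- h
  h
}
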