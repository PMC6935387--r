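# Self-contained synthetic dataset generator: genome FASTA, Gencode-style
# GTF, five rMATS-style event tables, expression TSV and a ground-truth
# manifest, with configurable planted effects (donor-strength deficit,
# intron-length shift, branch-point offset shift, stop-codon classes).
#
# Construction invariants the rest of the package relies on:
#  * every exon's CDS portion is a multiple of 3 and the CDS starts in
#    frame, so the codon phase at every intron is 0;
#  * every intron starts GT..ends AG, with the 3 last intronic bases CAG;
#  * the acceptor polypyrimidine tract contains no adenosine, and all other
#    A's in the 3'SS-proximal branch-point scan window are masked, so the
#    single planted branch 7-mer is the unique best-scoring candidate.

#' Generator donor position probability matrix
#'
#' 9 positions (3 exonic + 6 intronic), GT at intron positions +1/+2 fixed.
#' @return 9 x 4 matrix of base probabilities, columns A/C/G/T.
#' @export
generator_donor_pwm <- function() {
  m <- rbind(
    c(.33, .37, .18, .12),
    c(.60, .13, .12, .15),
    c(.09, .03, .80, .08),
    c(0, 0, 1, 0),          # +1 G
    c(0, 0, 0, 1),          # +2 T
    c(.60, .02, .35, .03),
    c(.70, .08, .12, .10),
    c(.06, .05, .82, .07),
    c(.15, .18, .22, .45)
  )
  colnames(m) <- c("A", "C", "G", "T")
  m
}

#' Generator acceptor position probability matrix
#'
#' 23 positions (20 intronic + 3 exonic). The polypyrimidine tract
#' (positions 1-17) carries no adenosine; positions 18-20 are the fixed
#' C-A-G 3' splice site.
#' @return 23 x 4 matrix of base probabilities, columns A/C/G/T.
#' @export
generator_acceptor_pwm <- function() {
  ppt <- matrix(rep(c(0, .45, .10, .45), 17), ncol = 4, byrow = TRUE)
  m <- rbind(
    ppt,
    c(0, 1, 0, 0),           # -3 C
    c(1, 0, 0, 0),           # -2 A
    c(0, 0, 1, 0),           # -1 G
    c(.22, .13, .52, .13),
    c(.28, .30, .20, .22),
    c(.25, .25, .25, .25)
  )
  colnames(m) <- c("A", "C", "G", "T")
  m
}

# Expected log2-odds (vs uniform) of windows drawn from `draw_pwm` scored
# with `score_pwm`'s log-odds. 0 * log(0) treated as 0.
.pwm_expected_bits <- function(draw_pwm, score_pwm) {
  lod <- log2(score_pwm / 0.25)
  contrib <- draw_pwm * lod
  contrib[draw_pwm == 0] <- 0
  sum(contrib)
}

#' Weaken a generator PWM by a target bit deficit
#'
#' Mixes each position's distribution with the uniform distribution over
#' its own support (bases with nonzero probability; fixed single-base
#' positions are untouched), choosing the mixing weight numerically so the
#' expected score of sampled windows - under the ORIGINAL matrix's
#' log2-odds versus uniform background - drops by `delta_bits`.
#'
#' @param pwm Position probability matrix.
#' @param delta_bits Target expected-score deficit in bits (>= 0). Clamped
#'   with a warning if the support-restricted mixing cannot realize it.
#' @return Weakened matrix of the same shape.
#' @export
weaken_pwm <- function(pwm, delta_bits) {
  if (delta_bits <= 0) return(pwm)
  u <- t(apply(pwm, 1, function(p) {
    s <- p > 0
    ifelse(s, 1 / sum(s), 0)
  }))
  mix <- function(lambda) (1 - lambda) * pwm + lambda * u
  e0 <- .pwm_expected_bits(pwm, pwm)
  f <- function(lambda) (e0 - .pwm_expected_bits(mix(lambda), pwm)) - delta_bits
  if (f(1) < 0) {
    warning("requested deficit ", delta_bits,
            " bits exceeds the achievable ", round(e0 - .pwm_expected_bits(u, pwm), 2),
            "; using full flattening")
    return(mix(1))
  }
  lambda <- stats::uniroot(f, c(0, 1), tol = 1e-9)$root
  mix(lambda)
}

#' Sample window sequences from a PWM
#' @param pwm Position probability matrix (positions x A/C/G/T).
#' @param n Number of windows.
#' @return Character vector of `n` windows.
#' @export
sample_windows <- function(pwm, n) {
  bases <- colnames(pwm)
  mat <- vapply(seq_len(nrow(pwm)), function(p)
    sample(bases, n, replace = TRUE, prob = pwm[p, ]), character(n))
  if (n == 1L) paste(mat, collapse = "") else apply(mat, 1, paste, collapse = "")
}

.rand_bases <- function(n, gc) {
  if (n <= 0L) return(character(0))
  sample(c("A", "C", "G", "T"), n, replace = TRUE,
         prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
}

# n_codons random stop-free codons (characters, length 3*n).
.rand_codons <- function(n_codons, gc) {
  if (n_codons <= 0L) return(character(0))
  b <- .rand_bases(3L * n_codons, gc)
  starts <- seq(1L, length(b), by = 3L)
  for (s in starts) {
    if (paste(b[s:(s + 2L)], collapse = "") %in% c("TAA", "TAG", "TGA"))
      b[s] <- "C"
  }
  b
}

.draw_lnorm_len <- function(n, params, clip) {
  v <- round(stats::rlnorm(n, meanlog = params[[1]], sdlog = params[[2]]))
  pmin(pmax(v, clip[1]), clip[2])
}

#' Synthetic dataset configuration
#'
#' Defaults define the study conditions the pipeline is validated under:
#' event-cohort retained introns are log-normal with median 300 nt versus
#' 1500 nt for background/control introns, event donor sites carry a 3-bit
#' expected-score deficit, and 93% of retained-intron events contain an
#' in-frame stop (2% a downstream frameshift PTC). Fixture sizes (400
#' genes) keep a full pipeline run fast; the external-pool default of 1200
#' genes lives in the pipeline configuration and is overridden to fit the
#' fixture scale there.
#'
#' @param seed Integer seed; mandatory.
#' @param n_genes Total gene count (default 400).
#' @param exons_per_gene Integer range, default `c(4, 9)`.
#' @param exon_len Range of exon CDS lengths in nt (rounded up to a
#'   multiple of 3), default `c(75, 180)`.
#' @param utr_len UTR length on the first/last exon, default 12.
#' @param intron_len List of `c(meanlog, sdlog)` per cohort:
#'   `background`, `ri_increased`, `ri_decreased`.
#' @param intron_clip Intron length clip range, default `c(80, 8000)`.
#' @param donor_strength_delta_bits Donor deficit of event sites, default 3.
#' @param acceptor_strength_delta_bits Acceptor deficit, default 0.
#' @param bp_offset List of offset ranges `background` and `event`
#'   (nt from branch A to intron 3' end).
#' @param gc_target Background base-composition GC fraction, default 0.45.
#' @param n_ri_events,n_se_events Event counts (split evenly between
#'   increased/decreased direction), defaults 60 each.
#' @param n_other_events Events per A5SS/A3SS/MXE table, default 4.
#' @param n_decoy_rows Non-significant decoy rows per table, default 3.
#' @param frac_ri_with_inframe_stop Fraction of RI events planted with an
#'   in-frame stop, default 0.93 (applied exactly: `round(frac * n)`).
#' @param frac_ri_frameshift Fraction planted as frameshift PTC, default 0.02.
#' @param expression `c(meanlog, sdlog)` of gene expression, default
#'   `c(log(50), 1.5)`.
#' @param n_mito_genes Genes on the mitochondrial decoy chromosome, default 3.
#' @param genes_per_chrom Nuclear genes per synthetic chromosome, default 50.
#' @param null_mode If TRUE, all planted effects are forced to zero (event
#'   cohorts drawn from the background distributions).
#' @return Object of class `sp_synth_config`.
#' @export
synthetic_config <- function(seed,
                             n_genes = 400L,
                             exons_per_gene = c(4L, 9L),
                             exon_len = c(75L, 180L),
                             utr_len = 12L,
                             intron_len = list(background = c(log(1500), 0.6),
                                               ri_increased = c(log(300), 0.5),
                                               ri_decreased = c(log(1500), 0.6)),
                             intron_clip = c(80L, 8000L),
                             donor_strength_delta_bits = 3.0,
                             acceptor_strength_delta_bits = 0.0,
                             bp_offset = list(background = c(20L, 50L),
                                              event = c(25L, 70L)),
                             gc_target = 0.45,
                             n_ri_events = 60L,
                             n_se_events = 60L,
                             n_other_events = 4L,
                             n_decoy_rows = 3L,
                             frac_ri_with_inframe_stop = 0.93,
                             frac_ri_frameshift = 0.02,
                             expression = c(log(50), 1.5),
                             n_mito_genes = 3L,
                             genes_per_chrom = 50L,
                             null_mode = FALSE) {
  if (missing(seed)) stop("synthetic_config requires a seed")
  cfg <- list(seed = as.integer(seed), n_genes = as.integer(n_genes),
              exons_per_gene = exons_per_gene, exon_len = exon_len,
              utr_len = utr_len, intron_len = intron_len,
              intron_clip = intron_clip,
              donor_strength_delta_bits = donor_strength_delta_bits,
              acceptor_strength_delta_bits = acceptor_strength_delta_bits,
              bp_offset = bp_offset, gc_target = gc_target,
              n_ri_events = as.integer(n_ri_events),
              n_se_events = as.integer(n_se_events),
              n_other_events = as.integer(n_other_events),
              n_decoy_rows = as.integer(n_decoy_rows),
              frac_ri_with_inframe_stop = frac_ri_with_inframe_stop,
              frac_ri_frameshift = frac_ri_frameshift,
              expression = expression, n_mito_genes = as.integer(n_mito_genes),
              genes_per_chrom = as.integer(genes_per_chrom),
              null_mode = isTRUE(null_mode))
  if (cfg$null_mode) {
    cfg$donor_strength_delta_bits <- 0
    cfg$acceptor_strength_delta_bits <- 0
    cfg$intron_len$ri_increased <- cfg$intron_len$background
    cfg$intron_len$ri_decreased <- cfg$intron_len$background
    cfg$bp_offset$event <- cfg$bp_offset$background
  }
  n_special <- cfg$n_ri_events + cfg$n_se_events + 3L * cfg$n_other_events +
    5L * cfg$n_decoy_rows + cfg$n_mito_genes + 6L
  if (cfg$n_genes < n_special + 20L)
    stop("config infeasible: n_genes = ", cfg$n_genes,
         " cannot host ", n_special, " special genes plus a background pool")
  structure(cfg, class = "sp_synth_config")
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

# Build one intron (character vector, transcript orientation) with planted
# donor/acceptor windows, masked branch-point scan window and a unique
# planted branch 7-mer. Returns the chars plus ground truth.
.make_intron <- function(L, donor_pwm, acceptor_pwm, bp_off, bp_7mer, gc,
                         search_min = 15L, search_max = 500L,
                         frame0_clean = FALSE) {
  stopifnot(L >= 60L)
  chars <- .rand_bases(L, gc)
  # donor: resample until the 3 exonic nt are not a stop codon (they replace
  # the final codon of the upstream exon); with frame0_clean also keep
  # intron positions +4..+6 (the second phase-0 codon) stop-free
  repeat {
    d9 <- strsplit(sample_windows(donor_pwm, 1L), "")[[1]]
    if (paste(d9[1:3], collapse = "") %in% STOP_CODONS) next
    if (frame0_clean && paste(d9[7:9], collapse = "") %in% STOP_CODONS) next
    break
  }
  repeat {
    a23 <- strsplit(sample_windows(acceptor_pwm, 1L), "")[[1]]
    if (!(paste(a23[21:23], collapse = "") %in% STOP_CODONS)) break
  }
  chars[1:6] <- d9[4:9]
  chars[(L - 19L):L] <- a23[1:20]
  # mask competing branch A's in the scan window (acceptor tract is A-free)
  lo <- max(7L, L - search_max)
  hi <- L - search_min
  if (hi >= lo) {
    idx <- lo:hi
    isA <- idx[chars[idx] == "A"]
    if (length(isA) > 0L)
      chars[isA] <- sample(c("C", "T"), length(isA), replace = TRUE)
  }
  # plant the branch 7-mer (A at position 5 of the 7-mer)
  bp_off <- min(max(bp_off, search_min), L - 11L)
  i_bp <- L - bp_off
  chars[(i_bp - 4L):(i_bp + 2L)] <- strsplit(bp_7mer, "")[[1]]
  list(chars = chars,
       donor_window = paste(d9, collapse = ""),
       acceptor_window = paste(a23, collapse = ""),
       exon_donor_triplet = d9[1:3],
       exon_acceptor_triplet = a23[21:23],
       bp_offset = bp_off, i_bp = i_bp)
}

# Replace codon-aligned stop codons in an intron (phase 0), never touching
# the donor head, acceptor tail or branch 7-mer.
.scrub_intron_stops <- function(chars, i_bp) {
  L <- length(chars)
  protected <- c(1:6, (i_bp - 4L):(i_bp + 2L), (L - 19L):L)
  for (s in seq(1L, L - 2L, by = 3L)) {
    if (paste(chars[s:(s + 2L)], collapse = "") %in% STOP_CODONS &&
        !any((s:(s + 2L)) %in% protected))
      chars[s] <- "C"
  }
  chars
}

# Plant an in-frame (phase-0) TAA inside the intron, avoiding the planted
# elements.
.plant_intron_stop <- function(chars, i_bp) {
  L <- length(chars)
  for (s in seq(7L, L - 22L, by = 3L)) {
    if (s + 2L < i_bp - 4L || s > i_bp + 2L) {
      chars[s:(s + 2L)] <- c("T", "A", "A")
      return(chars)
    }
  }
  stop("no room to plant an in-frame stop in a ", L, " nt intron")
}

# --- gene construction -----------------------------------------------------

# Builds one gene in transcript orientation. `role` carries type
# ("background", "ri", "se"), direction, consequence class, and structural
# requirements. Returns sequence, exon/CDS layout (within-gene transcript
# coordinates) and per-intron ground truth.
.build_gene <- function(gid, role, cfg, pwms) {
  er <- cfg$exons_per_gene
  E <- sample(er[1]:er[2], 1L)
  if (identical(role$type, "se")) E <- max(E, 4L)
  if (identical(role$type, "mxe")) E <- max(E, 4L)
  strand <- sample(c("+", "-"), 1L)

  # focal element
  focal_intron <- NA_integer_
  focal_exon <- NA_integer_
  if (identical(role$type, "ri")) focal_intron <- sample(seq_len(E - 1L), 1L)
  if (identical(role$type, "se")) {
    focal_exon <- sample(2:(E - 1L), 1L)
    focal_intron <- focal_exon - 1L  # upstream intron; downstream is focal_exon
  }

  exon_cds <- vapply(seq_len(E), function(i) {
    c <- sample(cfg$exon_len[1]:cfg$exon_len[2], 1L)
    as.integer(c + (3L - c %% 3L) %% 3L)
  }, integer(1))

  intron_L <- integer(E - 1L)
  for (i in seq_len(E - 1L)) {
    cohort <- "background"
    if (identical(role$type, "ri") && i == focal_intron) {
      cohort <- if (identical(role$direction, "increased_in_mutant"))
        "ri_increased" else "ri_decreased"
    }
    intron_L[i] <- .draw_lnorm_len(1L, cfg$intron_len[[cohort]], cfg$intron_clip)
  }
  # consequence class needs a specific length residue for the focal RI intron
  if (identical(role$type, "ri")) {
    L <- intron_L[focal_intron]
    if (identical(role$consequence, "no_ptc")) {
      L <- L - L %% 3L
    } else if (identical(role$consequence, "frameshift_ptc_downstream")) {
      L <- L - ((L - 1L) %% 3L)  # L %% 3 == 1
    }
    while (L < cfg$intron_clip[1]) L <- L + 3L  # keep the frame residue
    intron_L[focal_intron] <- as.integer(L)
  }

  weak_donor <- pwms$donor_weak
  weak_acceptor <- pwms$acceptor_weak
  is_weak_donor <- function(i) {
    (identical(role$type, "ri") && i == focal_intron) ||
      (identical(role$type, "se") && i == focal_exon)       # focal exon's 5'SS
  }
  is_weak_acceptor <- function(i) {
    (identical(role$type, "ri") && i == focal_intron) ||
      (identical(role$type, "se") && i == focal_exon - 1L)  # focal exon's 3'SS
  }
  event_bp <- function(i) {
    if (identical(role$type, "ri") && i == focal_intron) return(TRUE)
    if (identical(role$type, "se") && i %in% c(focal_exon - 1L, focal_exon))
      return(TRUE)
    FALSE
  }

  exon_parts <- vector("list", E)
  for (i in seq_len(E)) {
    cds <- .rand_codons(exon_cds[i] / 3L, cfg$gc_target)
    if (i == 1L) cds <- c(.rand_bases(cfg$utr_len, cfg$gc_target), cds)
    if (i == E) cds <- c(cds, c("T", "A", "A"), .rand_bases(cfg$utr_len, cfg$gc_target))
    exon_parts[[i]] <- cds
  }

  intron_parts <- vector("list", E - 1L)
  truth <- vector("list", E - 1L)
  for (i in seq_len(E - 1L)) {
    dp <- if (is_weak_donor(i)) weak_donor else pwms$donor
    ap <- if (is_weak_acceptor(i)) weak_acceptor else pwms$acceptor
    rng <- if (event_bp(i)) cfg$bp_offset$event else cfg$bp_offset$background
    off <- sample(rng[1]:rng[2], 1L)
    variant <- "TACTAAC"
    needs_clean <- identical(role$type, "ri") && i == focal_intron &&
      role$consequence %in% c("no_ptc", "frameshift_ptc_downstream")
    if (needs_clean) variant <- "TACCAAC"  # stop-free in every reading frame
    mi <- .make_intron(intron_L[i], dp, ap, off, variant, cfg$gc_target,
                       frame0_clean = needs_clean)
    if (identical(role$type, "ri") && i == focal_intron) {
      if (identical(role$consequence, "in_frame_stop")) {
        mi$chars <- .plant_intron_stop(mi$chars, mi$i_bp)
      } else {
        mi$chars <- .scrub_intron_stops(mi$chars, mi$i_bp)
      }
    }
    # stamp the exonic halves of the splice windows
    np <- length(exon_parts[[i]])
    exon_parts[[i]][(np - 2L):np] <- mi$exon_donor_triplet
    exon_parts[[i + 1L]][1:3] <- mi$exon_acceptor_triplet
    intron_parts[[i]] <- mi$chars
    truth[[i]] <- list(length = intron_L[i], bp_offset = mi$bp_offset,
                       donor_window = mi$donor_window,
                       acceptor_window = mi$acceptor_window)
  }
  # frameshift PTC: plant a shifted-frame stop early in the downstream exon
  if (identical(role$type, "ri") &&
      identical(role$consequence, "frameshift_ptc_downstream")) {
    # L %% 3 == 1 -> shifted codons start at exon offsets 3, 6, 9, ...
    exon_parts[[focal_intron + 1L]][6:8] <- c("T", "A", "A")
  }

  # assemble transcript-orientation sequence and within-gene coordinates
  parts <- list()
  exon_bounds <- matrix(0L, E, 2L)
  pos <- 0L
  for (i in seq_len(E)) {
    exon_bounds[i, ] <- c(pos, pos + length(exon_parts[[i]]))
    parts[[length(parts) + 1L]] <- exon_parts[[i]]
    pos <- pos + length(exon_parts[[i]])
    if (i < E) {
      parts[[length(parts) + 1L]] <- intron_parts[[i]]
      pos <- pos + length(intron_parts[[i]])
    }
  }
  seq_chars <- unlist(parts)
  # CDS within-gene coordinates (transcript orientation)
  cds_bounds <- matrix(0L, E, 2L)
  for (i in seq_len(E)) {
    s <- exon_bounds[i, 1]
    e <- exon_bounds[i, 2]
    if (i == 1L) s <- s + cfg$utr_len
    if (i == E) e <- exon_bounds[i, 1] + exon_cds[i]  # excludes stop + UTR
    cds_bounds[i, ] <- c(s, e)
  }

  list(gid = gid, role = role, strand = strand, n_exons = E,
       seq = paste(seq_chars, collapse = ""),
       length = length(seq_chars),
       exon_bounds = exon_bounds, cds_bounds = cds_bounds,
       exon_cds = exon_cds,
       focal_intron = focal_intron, focal_exon = focal_exon,
       intron_truth = truth)
}

# Within-gene transcript interval [a, b) -> genomic [start, end) given the
# gene's placement.
.g2genomic <- function(a, b, gene_start, gene_len, strand) {
  if (strand == "+") as.integer(c(gene_start + a, gene_start + b))
  else as.integer(c(gene_start + gene_len - b, gene_start + gene_len - a))
}

#' Generate a synthetic dataset
#'
#' Writes `genome.fa`, `annotation.gtf`, the five rMATS-style tables
#' (`<KIND>.MATS.JCEC.txt`), `expression.tsv`, `manifest_events.tsv` and
#' `manifest_genes.tsv` into `outdir`. Planted events are guaranteed to
#' pass the p < 0.05 / FDR < 0.05 filter and decoy rows to fail it.
#'
#' @param config From [synthetic_config()].
#' @param outdir Output directory (created if needed).
#' @return List with `dir`, `paths` (named file paths), `manifest_events`,
#'   `manifest_genes` and the `config`.
#' @export
generate_dataset <- function(config, outdir) {
  stopifnot(inherits(config, "sp_synth_config"))
  cfg <- config
  set.seed(cfg$seed)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

  pwms <- list(donor = generator_donor_pwm(), acceptor = generator_acceptor_pwm())
  pwms$donor_weak <- weaken_pwm(pwms$donor, cfg$donor_strength_delta_bits)
  pwms$acceptor_weak <- weaken_pwm(pwms$acceptor, cfg$acceptor_strength_delta_bits)

  # --- gene plan -----------------------------------------------------------
  n_ri_inc <- cfg$n_ri_events %/% 2L
  n_ri_dec <- cfg$n_ri_events - n_ri_inc
  n_se_inc <- cfg$n_se_events %/% 2L
  n_se_dec <- cfg$n_se_events - n_se_inc

  # exact stop-class planting across the pooled RI event list
  n_stop <- round(cfg$frac_ri_with_inframe_stop * cfg$n_ri_events)
  n_fs <- min(round(cfg$frac_ri_frameshift * cfg$n_ri_events),
              cfg$n_ri_events - n_stop)
  classes <- c(rep("in_frame_stop", n_stop),
               rep("frameshift_ptc_downstream", n_fs),
               rep("no_ptc", cfg$n_ri_events - n_stop - n_fs))
  classes <- sample(classes)  # interleave across directions

  roles <- list()
  add_role <- function(r, n) {
    for (i in seq_len(n)) roles[[length(roles) + 1L]] <<- r
    invisible(NULL)
  }
  for (i in seq_len(n_ri_inc)) roles[[length(roles) + 1L]] <-
    list(type = "ri", direction = "increased_in_mutant", consequence = classes[i])
  for (i in seq_len(n_ri_dec)) roles[[length(roles) + 1L]] <-
    list(type = "ri", direction = "decreased_in_mutant",
         consequence = classes[n_ri_inc + i])
  add_role(list(type = "se", direction = "increased_in_mutant"), n_se_inc)
  add_role(list(type = "se", direction = "decreased_in_mutant"), n_se_dec)
  for (k in c("a5ss", "a3ss", "mxe"))
    add_role(list(type = k), cfg$n_other_events)
  add_role(list(type = "decoy"), 5L * cfg$n_decoy_rows)
  add_role(list(type = "mito"), cfg$n_mito_genes)
  add_role(list(type = "lnc"), 3L)
  add_role(list(type = "no_tsl"), 3L)
  n_bg <- cfg$n_genes - length(roles)
  add_role(list(type = "background"), n_bg)

  gids <- sprintf("SYNG%04d", seq_along(roles))
  genes <- vector("list", length(roles))
  for (i in seq_along(roles)) {
    r <- roles[[i]]
    if (r$type %in% c("se")) {
      genes[[i]] <- .build_gene(gids[i], r, cfg, pwms)
    } else if (r$type == "ri") {
      genes[[i]] <- .build_gene(gids[i], r, cfg, pwms)
    } else {
      # decoy genes must support a 4-exon MXE row; mxe genes likewise
      rr <- r; rr$type <- if (r$type %in% c("mxe", "decoy")) "mxe" else "background"
      g <- .build_gene(gids[i], rr, cfg, pwms)
      g$role <- r
      genes[[i]] <- g
    }
  }

  # --- chromosome placement ------------------------------------------------
  spacer <- 200L
  is_mito <- vapply(genes, function(g) identical(g$role$type, "mito"), logical(1))
  nuclear <- which(!is_mito)
  chrom_of <- character(length(genes))
  gene_start <- integer(length(genes))
  chrom_seqs <- list()
  for (ci in seq_len(ceiling(length(nuclear) / cfg$genes_per_chrom))) {
    members <- nuclear[((ci - 1L) * cfg$genes_per_chrom + 1L):
                         min(ci * cfg$genes_per_chrom, length(nuclear))]
    cname <- paste0("chrS", ci)
    pos <- spacer
    pieces <- character(0)
    for (gi in members) {
      g <- genes[[gi]]
      chrom_of[gi] <- cname
      gene_start[gi] <- pos
      s <- g$seq
      if (g$strand == "-") s <- revcomp(s)
      pieces <- c(pieces, strrep("N", if (length(pieces) == 0L) spacer else spacer), s)
      pos <- pos + g$length + spacer
    }
    chrom_seqs[[cname]] <- paste(c(pieces, strrep("N", spacer)), collapse = "")
  }
  if (any(is_mito)) {
    pos <- spacer
    pieces <- character(0)
    for (gi in which(is_mito)) {
      g <- genes[[gi]]
      chrom_of[gi] <- "chrM"
      gene_start[gi] <- pos
      s <- g$seq
      if (g$strand == "-") s <- revcomp(s)
      pieces <- c(pieces, strrep("N", spacer), s)
      pos <- pos + g$length + spacer
    }
    chrom_seqs[["chrM"]] <- paste(c(pieces, strrep("N", spacer)), collapse = "")
  }

  # genomic exon/intron coordinates per gene
  for (gi in seq_along(genes)) {
    g <- genes[[gi]]
    E <- g$n_exons
    ex <- t(vapply(seq_len(E), function(i)
      .g2genomic(g$exon_bounds[i, 1], g$exon_bounds[i, 2],
                 gene_start[gi], g$length, g$strand), integer(2)))
    cds <- t(vapply(seq_len(E), function(i)
      .g2genomic(g$cds_bounds[i, 1], g$cds_bounds[i, 2],
                 gene_start[gi], g$length, g$strand), integer(2)))
    ord <- order(ex[, 1])
    genes[[gi]]$genomic_exons <- ex[ord, , drop = FALSE]     # genomic order
    genes[[gi]]$genomic_cds <- cds[order(cds[, 1]), , drop = FALSE]
    genes[[gi]]$tx_exon_genomic <- ex                        # transcript order
    genes[[gi]]$chrom <- chrom_of[gi]
  }

  # --- expression ----------------------------------------------------------
  expr_val <- stats::rlnorm(length(genes), cfg$expression[1], cfg$expression[2])
  if (any(is_mito)) {
    top <- max(expr_val)
    expr_val[is_mito] <- top * seq(1.5, 1.6, length.out = sum(is_mito))
  }

  # --- rMATS tables --------------------------------------------------------
  sig_p <- function(n) stats::runif(n, 1e-6, 0.04)
  tx_exon <- function(g, i) g$tx_exon_genomic[i, ]  # transcript-order exon i

  ev_rows <- list(SE = list(), RI = list(), A5SS = list(), A3SS = list(),
                  MXE = list())
  manifest <- list()
  next_id <- c(SE = 0L, RI = 0L, A5SS = 0L, A3SS = 0L, MXE = 0L)
  push_row <- function(kind, row) {
    next_id[kind] <<- next_id[kind] + 1L
    row$ID <- next_id[kind]
    ev_rows[[kind]][[length(ev_rows[[kind]]) + 1L]] <<- row
    row$ID
  }
  inc_pair <- function(direction) {
    # IncLevel1 - IncLevel2 with group 1 = WT; "increased_in_mutant" means
    # inclusion higher in group 2
    d <- stats::runif(1, 0.1, 0.5)
    if (identical(direction, "increased_in_mutant")) d <- -d
    i2 <- 0.5 - d / 2; i1 <- 0.5 + d / 2
    list(i1 = i1, i2 = i2, d = d)
  }

  for (gi in seq_along(genes)) {
    g <- genes[[gi]]
    r <- g$role
    if (r$type == "ri") {
      j <- g$focal_intron
      up <- tx_exon(g, j); dn <- tx_exon(g, j + 1L)
      ip <- inc_pair(r$direction)
      id <- push_row("RI", list(
        GeneID = g$gid, geneSymbol = g$gid, chr = g$chrom, strand = g$strand,
        riExonStart_0base = min(up[1], dn[1]), riExonEnd = max(up[2], dn[2]),
        upstreamES = up[1], upstreamEE = up[2],
        downstreamES = dn[1], downstreamEE = dn[2],
        PValue = sig_p(1), FDR = sig_p(1),
        IncLevel1 = sprintf("%.3f,%.3f", ip$i1, ip$i1),
        IncLevel2 = sprintf("%.3f,%.3f", ip$i2, ip$i2),
        IncLevelDifference = round(ip$d, 3)))
      tr <- g$intron_truth[[j]]
      iv <- sort(c(.g2genomic(g$exon_bounds[j, 2],
                              g$exon_bounds[j, 2] + tr$length,
                              gene_start[gi], g$length, g$strand)))
      manifest[[length(manifest) + 1L]] <- data.frame(
        event_id = paste0("RI_", id), kind = "RI", direction = r$direction,
        group = if (r$direction == "increased_in_mutant") "IRI" else "DRI",
        gene_id = g$gid, chrom = g$chrom, strand = g$strand,
        focal_start = iv[1], focal_end = iv[2],
        focal_length = tr$length,
        bp_offset = tr$bp_offset, bp_offset_downstream = NA_integer_,
        donor_window = tr$donor_window, acceptor_window = tr$acceptor_window,
        consequence = r$consequence, stringsAsFactors = FALSE)
    } else if (r$type == "se") {
      j <- g$focal_exon
      up <- tx_exon(g, j - 1L); fo <- tx_exon(g, j); dn <- tx_exon(g, j + 1L)
      # inclusion = exon inclusion; increased skipping = decreased inclusion
      incl_dir <- if (r$direction == "increased_in_mutant")
        "decreased_in_mutant" else "increased_in_mutant"
      # r$direction for SE roles encodes skipping; store inclusion direction
      ip <- inc_pair(incl_dir)
      id <- push_row("SE", list(
        GeneID = g$gid, geneSymbol = g$gid, chr = g$chrom, strand = g$strand,
        exonStart_0base = fo[1], exonEnd = fo[2],
        upstreamES = up[1], upstreamEE = up[2],
        downstreamES = dn[1], downstreamEE = dn[2],
        PValue = sig_p(1), FDR = sig_p(1),
        IncLevel1 = sprintf("%.3f,%.3f", ip$i1, ip$i1),
        IncLevel2 = sprintf("%.3f,%.3f", ip$i2, ip$i2),
        IncLevelDifference = round(ip$d, 3)))
      tr_up <- g$intron_truth[[j - 1L]]
      tr_dn <- g$intron_truth[[j]]
      manifest[[length(manifest) + 1L]] <- data.frame(
        event_id = paste0("SE_", id), kind = "SE",
        direction = incl_dir,
        group = if (r$direction == "increased_in_mutant") "ISE" else "DSE",
        gene_id = g$gid, chrom = g$chrom, strand = g$strand,
        focal_start = fo[1], focal_end = fo[2],
        focal_length = fo[2] - fo[1],
        bp_offset = tr_up$bp_offset, bp_offset_downstream = tr_dn$bp_offset,
        donor_window = tr_dn$donor_window, acceptor_window = tr_up$acceptor_window,
        consequence = NA_character_, stringsAsFactors = FALSE)
    } else if (r$type %in% c("a5ss", "a3ss")) {
      kind <- toupper(r$type)
      # long form extends exon 1 (A5SS, donor side) or exon 2 (A3SS,
      # acceptor side) 9 nt into intron 1; coordinates only
      e1 <- tx_exon(g, 1L); e2 <- tx_exon(g, 2L)
      if (kind == "A5SS") {
        long <- if (g$strand == "+") c(e1[1], e1[2] + 9L) else c(e1[1] - 9L, e1[2])
        short <- e1; flank <- e2
      } else {
        long <- if (g$strand == "+") c(e2[1] - 9L, e2[2]) else c(e2[1], e2[2] + 9L)
        short <- e2; flank <- e1
      }
      d <- sample(c(-1, 1), 1) * stats::runif(1, 0.1, 0.4)
      push_row(kind, list(
        GeneID = g$gid, geneSymbol = g$gid, chr = g$chrom, strand = g$strand,
        longExonStart_0base = long[1], longExonEnd = long[2],
        shortES = short[1], shortEE = short[2],
        flankingES = flank[1], flankingEE = flank[2],
        PValue = sig_p(1), FDR = sig_p(1),
        IncLevel1 = "0.6,0.6", IncLevel2 = "0.4,0.4",
        IncLevelDifference = round(d, 3)))
    } else if (r$type == "mxe") {
      e1 <- tx_exon(g, 1L); x1 <- tx_exon(g, 2L)
      x2 <- tx_exon(g, 3L); e4 <- tx_exon(g, 4L)
      d <- sample(c(-1, 1), 1) * stats::runif(1, 0.1, 0.4)
      push_row("MXE", list(
        GeneID = g$gid, geneSymbol = g$gid, chr = g$chrom, strand = g$strand,
        `1stExonStart_0base` = min(x1[1], x2[1]), `1stExonEnd` = min(x1[2], x2[2]),
        `2ndExonStart_0base` = max(x1[1], x2[1]), `2ndExonEnd` = max(x1[2], x2[2]),
        upstreamES = e1[1], upstreamEE = e1[2],
        downstreamES = e4[1], downstreamEE = e4[2],
        PValue = sig_p(1), FDR = sig_p(1),
        IncLevel1 = "0.6,0.6", IncLevel2 = "0.4,0.4",
        IncLevelDifference = round(d, 3)))
    }
  }
  # decoy rows: non-significant entries referencing decoy genes
  decoys <- which(vapply(genes, function(g) identical(g$role$type, "decoy"),
                         logical(1)))
  di <- 1L
  for (kind in c("SE", "RI", "A5SS", "A3SS", "MXE")) {
    for (k in seq_len(cfg$n_decoy_rows)) {
      g <- genes[[decoys[di]]]; di <- di + 1L
      e1 <- tx_exon(g, 1L); e2 <- tx_exon(g, 2L); e3 <- tx_exon(g, 3L)
      # alternate between (p >= .05) and (p < .05 but FDR >= .05)
      if (k %% 2L == 0L) { p <- stats::runif(1, 0.2, 0.9); q <- stats::runif(1, 0.3, 0.95) }
      else { p <- stats::runif(1, 0.01, 0.049); q <- stats::runif(1, 0.1, 0.9) }
      row <- switch(kind,
        SE = list(GeneID = g$gid, geneSymbol = g$gid, chr = g$chrom,
                  strand = g$strand, exonStart_0base = e2[1], exonEnd = e2[2],
                  upstreamES = e1[1], upstreamEE = e1[2],
                  downstreamES = e3[1], downstreamEE = e3[2]),
        RI = list(GeneID = g$gid, geneSymbol = g$gid, chr = g$chrom,
                  strand = g$strand,
                  riExonStart_0base = min(e1[1], e2[1]),
                  riExonEnd = max(e1[2], e2[2]),
                  upstreamES = e1[1], upstreamEE = e1[2],
                  downstreamES = e2[1], downstreamEE = e2[2]),
        A5SS = list(GeneID = g$gid, geneSymbol = g$gid, chr = g$chrom,
                    strand = g$strand,
                    longExonStart_0base = e1[1], longExonEnd = e1[2] + 9L,
                    shortES = e1[1], shortEE = e1[2],
                    flankingES = e2[1], flankingEE = e2[2]),
        A3SS = list(GeneID = g$gid, geneSymbol = g$gid, chr = g$chrom,
                    strand = g$strand,
                    longExonStart_0base = e2[1] - 9L, longExonEnd = e2[2],
                    shortES = e2[1], shortEE = e2[2],
                    flankingES = e1[1], flankingEE = e1[2]),
        MXE = list(GeneID = g$gid, geneSymbol = g$gid, chr = g$chrom,
                   strand = g$strand,
                   `1stExonStart_0base` = e2[1], `1stExonEnd` = e2[2],
                   `2ndExonStart_0base` = e3[1], `2ndExonEnd` = e3[2],
                   upstreamES = e1[1], upstreamEE = e1[2],
                   downstreamES = tx_exon(g, 4L)[1], downstreamEE = tx_exon(g, 4L)[2]))
      row$PValue <- p; row$FDR <- q
      row$IncLevel1 <- "0.5,0.5"; row$IncLevel2 <- "0.5,0.5"
      row$IncLevelDifference <- round(sample(c(-1, 1), 1) * stats::runif(1, 0.01, 0.1), 3)
      push_row(kind, row)
    }
  }

  # --- write files ---------------------------------------------------------
  paths <- list(
    genome = file.path(outdir, "genome.fa"),
    gtf = file.path(outdir, "annotation.gtf"),
    expression = file.path(outdir, "expression.tsv"),
    manifest_events = file.path(outdir, "manifest_events.tsv"),
    manifest_genes = file.path(outdir, "manifest_genes.tsv")
  )
  for (kind in c("SE", "RI", "A5SS", "A3SS", "MXE"))
    paths[[kind]] <- file.path(outdir, paste0(kind, ".MATS.JCEC.txt"))

  gseq <- Biostrings::DNAStringSet(unlist(chrom_seqs))
  names(gseq) <- names(chrom_seqs)
  Biostrings::writeXStringSet(gseq, paths$genome, width = 70L)

  .write_gtf(genes, expr_val, paths$gtf)

  for (kind in c("SE", "RI", "A5SS", "A3SS", "MXE"))
    .write_rmats_table(ev_rows[[kind]], paths[[kind]])

  utils::write.table(
    data.frame(gene_id = gids, expression = signif(expr_val, 6)),
    paths$expression, sep = "\t", quote = FALSE, row.names = FALSE)

  manifest_events <- if (length(manifest) > 0L) do.call(rbind, manifest) else
    data.frame()
  utils::write.table(manifest_events, paths$manifest_events, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  manifest_genes <- data.frame(
    gene_id = gids,
    role = vapply(genes, function(g) g$role$type, character(1)),
    chrom = vapply(genes, function(g) g$chrom, character(1)),
    strand = vapply(genes, function(g) g$strand, character(1)),
    n_exons = vapply(genes, function(g) g$n_exons, integer(1)),
    expression = signif(expr_val, 6),
    stringsAsFactors = FALSE)
  utils::write.table(manifest_genes, paths$manifest_genes, sep = "\t",
                     quote = FALSE, row.names = FALSE)

  list(dir = outdir, paths = paths, manifest_events = manifest_events,
       manifest_genes = manifest_genes, config = cfg)
}

.write_gtf <- function(genes, expr_val, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (g in genes) {
    r <- g$role
    ttype <- if (identical(r$type, "lnc")) "lncRNA" else "protein_coding"
    tsl <- if (identical(r$type, "no_tsl")) "NA" else as.character(sample(1:3, 1))
    tid <- paste0(g$gid, ".t1")
    span <- range(g$genomic_exons)
    attr_gene <- sprintf('gene_id "%s"; gene_type "%s"; gene_name "%s";',
                         g$gid, ttype, g$gid)
    attr_tx <- sprintf(paste0('gene_id "%s"; transcript_id "%s"; gene_type "%s"; ',
                              'gene_name "%s"; transcript_type "%s"; ',
                              'transcript_support_level "%s";'),
                       g$gid, tid, ttype, g$gid, ttype, tsl)
    lines <- c(
      sprintf("%s\tsynth\tgene\t%d\t%d\t.\t%s\t.\t%s",
              g$chrom, span[1] + 1L, span[2], g$strand, attr_gene),
      sprintf("%s\tsynth\ttranscript\t%d\t%d\t.\t%s\t.\t%s",
              g$chrom, span[1] + 1L, span[2], g$strand, attr_tx))
    for (i in seq_len(nrow(g$genomic_exons))) {
      lines <- c(lines, sprintf(
        "%s\tsynth\texon\t%d\t%d\t.\t%s\t.\t%s exon_number %d;",
        g$chrom, g$genomic_exons[i, 1] + 1L, g$genomic_exons[i, 2],
        g$strand, attr_tx, i))
    }
    if (!identical(r$type, "lnc")) {
      for (i in seq_len(nrow(g$genomic_cds))) {
        lines <- c(lines, sprintf(
          "%s\tsynth\tCDS\t%d\t%d\t.\t%s\t0\t%s",
          g$chrom, g$genomic_cds[i, 1] + 1L, g$genomic_cds[i, 2],
          g$strand, attr_tx))
      }
    }
    writeLines(lines, con)
  }
}

.write_rmats_table <- function(rows, path) {
  if (length(rows) == 0L) {
    writeLines("ID\tGeneID", path)
    return(invisible(NULL))
  }
  cols <- c("ID", setdiff(names(rows[[1]]), "ID"))
  df <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, check.names = FALSE, stringsAsFactors = FALSE)))
  df <- df[, cols, drop = FALSE]
  for (cn in c("PValue", "FDR"))
    if (cn %in% names(df)) df[[cn]] <- as.character(signif(df[[cn]], 6))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Mirror a synthetic dataset
#'
#' Reverse-complements every chromosome, flips all coordinates
#' (`x -> L - x` on the 0-based half-open scale), and swaps strands in the
#' GTF, rMATS tables and event manifest. Mirroring twice restores the
#' original dataset; a pipeline run on the mirror must produce the same
#' feature values as on the original (the strand-symmetry oracle).
#'
#' @param indir Directory written by [generate_dataset()].
#' @param outdir Output directory.
#' @return Invisibly, the list of mirrored file paths.
#' @export
mirror_dataset <- function(indir, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  genome <- load_genome(file.path(indir, "genome.fa"))
  lens <- genome_lengths(genome)
  mirrored <- Biostrings::reverseComplement(genome)
  names(mirrored) <- names(genome)
  Biostrings::writeXStringSet(mirrored, file.path(outdir, "genome.fa"), width = 70L)

  flip_strand <- function(s) ifelse(s == "+", "-", ifelse(s == "-", "+", s))

  # GTF: 1-based closed [s, e] -> [L - e + 1, L - s + 1]
  gl <- readLines(file.path(indir, "annotation.gtf"))
  keep <- !grepl("^#", gl) & nzchar(gl)
  fields <- strsplit(gl[keep], "\t", fixed = TRUE)
  out <- vapply(fields, function(f) {
    L <- lens[[f[1]]]
    s <- as.integer(f[4]); e <- as.integer(f[5])
    f[4] <- as.character(L - e + 1L)
    f[5] <- as.character(L - s + 1L)
    f[7] <- flip_strand(f[7])
    paste(f, collapse = "\t")
  }, character(1))
  writeLines(out, file.path(outdir, "annotation.gtf"))

  # rMATS tables: 0-based half-open [s, e) -> [L - e, L - s)
  pair_cols <- list(
    SE = list(c("exonStart_0base", "exonEnd"), c("upstreamES", "upstreamEE"),
              c("downstreamES", "downstreamEE")),
    RI = list(c("riExonStart_0base", "riExonEnd"), c("upstreamES", "upstreamEE"),
              c("downstreamES", "downstreamEE")),
    A5SS = list(c("longExonStart_0base", "longExonEnd"), c("shortES", "shortEE"),
                c("flankingES", "flankingEE")),
    A3SS = list(c("longExonStart_0base", "longExonEnd"), c("shortES", "shortEE"),
                c("flankingES", "flankingEE")),
    MXE = list(c("1stExonStart_0base", "1stExonEnd"),
               c("2ndExonStart_0base", "2ndExonEnd"),
               c("upstreamES", "upstreamEE"), c("downstreamES", "downstreamEE"))
  )
  for (kind in names(pair_cols)) {
    fn <- paste0(kind, ".MATS.JCEC.txt")
    tab <- utils::read.delim(file.path(indir, fn), check.names = FALSE,
                             stringsAsFactors = FALSE, colClasses = "character")
    L <- lens[tab$chr]
    for (pc in pair_cols[[kind]]) {
      s <- as.integer(tab[[pc[1]]]); e <- as.integer(tab[[pc[2]]])
      tab[[pc[1]]] <- unname(L - e)
      tab[[pc[2]]] <- unname(L - s)
    }
    tab$strand <- flip_strand(tab$strand)
    utils::write.table(tab, file.path(outdir, fn), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }

  file.copy(file.path(indir, "expression.tsv"),
            file.path(outdir, "expression.tsv"), overwrite = TRUE)
  me_path <- file.path(indir, "manifest_events.tsv")
  if (file.exists(me_path)) {
    me <- utils::read.delim(me_path, stringsAsFactors = FALSE)
    if (nrow(me) > 0L) {
      L <- lens[me$chrom]
      s <- me$focal_start; e <- me$focal_end
      me$focal_start <- unname(L - e)
      me$focal_end <- unname(L - s)
      me$strand <- flip_strand(me$strand)
    }
    utils::write.table(me, file.path(outdir, "manifest_events.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  mg_path <- file.path(indir, "manifest_genes.tsv")
  if (file.exists(mg_path)) {
    mg <- utils::read.delim(mg_path, stringsAsFactors = FALSE)
    mg$strand <- flip_strand(mg$strand)
    utils::write.table(mg, file.path(outdir, "manifest_genes.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(list(dir = outdir))
}
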