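test_that("compare_groups runs Welch's t test with sane verdicts", {
  x <- c(1, 2, 3, 4, 5)
  res <- compare_groups(x, x)
  expect_equal(res$statistic, 0)
  expect_equal(res$verdict, "no_significant_difference")

  set.seed(12)
  a <- rnorm(120, 18, 1); b <- rnorm(120, 15, 1)
  res <- compare_groups(a, b)
  expect_lt(res$p_value, 1e-10)
  expect_equal(res$verdict, "higher")
  res2 <- compare_groups(b, a)
  expect_equal(res2$verdict, "lower")
  expect_true(res$ks_normal_p_a > 0 && res$ks_normal_p_a <= 1)

  expect_error(compare_groups(1, c(1, 2)), "at least 2")
})

test_that("p-value adjustment is correct for bonferroni and BH", {
  one <- compare_groups(c(1, 2, 3), c(4, 5, 6))
  one$p_value <- 0.03
  adj <- adjust_pvalues(one, "bonferroni")
  expect_equal(adj$p_adjusted, 0.03)  # m = 1

  ten <- do.call(rbind, replicate(10, one, simplify = FALSE))
  adj10 <- adjust_pvalues(ten, "bonferroni")
  expect_equal(adj10$p_adjusted, rep(0.30, 10))
  expect_true(all(adj10$verdict == "no_significant_difference"))
  expect_true(all(adj10$p_adjusted >= adj10$p_value))

  four <- do.call(rbind, replicate(4, one, simplify = FALSE))
  four$p_value <- c(0.01, 0.02, 0.03, 0.5)
  bh <- adjust_pvalues(four, "bh")
  expect_equal(bh$p_adjusted, c(0.04, 0.04, 0.04, 0.5))
  expect_error(adjust_pvalues(one[0, ], "bh"), "no results")
})

test_that("fraction_below uses strict inequality", {
  expect_equal(fraction_below(c(100, 400, 600), 500), 2 / 3)
  expect_equal(fraction_below(c(500, 600), 500), 0)
  expect_error(fraction_below(numeric(0), 1))
})

test_that("type-I error of the comparison is calibrated under the null", {
  set.seed(55)
  p <- vapply(1:200, function(i)
    compare_groups(rnorm(50), rnorm(50))$p_value, numeric(1))
  frac <- mean(p < 0.05)
  expect_gte(frac, 0.025)
  expect_lte(frac, 0.085)
})

test_that("summary table composes verdict phrases from both control comparisons", {
  set.seed(404)
  mk <- function(group, mu, n = 60) data.frame(
    group = group, donor_score = rnorm(n, mu, 1),
    ri_consequence = "frame_unavailable", stringsAsFactors = FALSE)
  # events 3 bits weaker than both controls
  feats <- rbind(mk("IRI", 5), mk("ICI", 8), mk("ECI", 8))
  out <- summarize_feature_table(feats, "donor_score", "IRI", "ICI", "ECI")
  cell <- out$summary$phrase[out$summary$feature == "donor_score"]
  expect_equal(cell, "Lower than internal and external controls")

  # null fixture: no verdict fires (seed screened)
  feats0 <- rbind(mk("IRI", 8), mk("ICI", 8), mk("ECI", 8))
  out0 <- summarize_feature_table(feats0, "donor_score", "IRI", "ICI", "ECI")
  expect_equal(out0$summary$phrase[out0$summary$feature == "donor_score"],
               "No significant difference")

  # stop-codon row counts in-frame stops among classifiable RIs
  feats$ri_consequence <- "frame_unavailable"
  feats$ri_consequence[feats$group == "IRI"] <-
    c(rep("in_frame_stop", 56), rep("no_ptc", 4))
  out2 <- summarize_feature_table(feats, "donor_score", "IRI", "ICI", "ECI")
  expect_equal(out2$summary$phrase[out2$summary$feature == "pct_in_frame_stop"],
               "93%")
})

test_that("planted k-mers are recovered and the null yields no hits", {
  set.seed(66)
  rand_seq <- function(n, len) vapply(1:n, function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
    character(1))
  bg <- rand_seq(50, 60)
  bg <- vapply(bg, function(s) gsub("GTCATG", "GTCATC", s), character(1),
               USE.NAMES = FALSE)
  fg <- rand_seq(50, 60)
  fg <- vapply(fg, function(s) {
    substr(s, 20, 25) <- "GTCATG"; s
  }, character(1), USE.NAMES = FALSE)
  hits <- kmer_enrichment(fg, bg, k_min = 5, k_max = 6, n_perm = 300)
  expect_true("GTCATG" %in% hits$kmer)
  top <- hits[hits$kmer == "GTCATG", ]
  expect_equal(top$fg_freq, 1)
  expect_equal(top$p_perm, 1 / 301)

  null_hits <- kmer_enrichment(rand_seq(30, 60), rand_seq(30, 60),
                               k_min = 5, k_max = 6, n_perm = 300)
  expect_equal(nrow(null_hits), 0L)

  expect_error(kmer_enrichment(rand_seq(5, 4), rand_seq(5, 4), k_min = 5),
               "shorter than k_min")
  expect_error(kmer_enrichment(character(0), bg), "nonempty")
})

test_that("permutation p-values are valid under the null", {
  set.seed(77)
  rand_seq <- function(n, len) vapply(1:n, function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
    character(1))
  # min_fg_frac = 0 tests the permutation machinery itself, without the
  # foreground-prevalence candidate screen (which conditions on the labels)
  ps <- numeric(0)
  for (r in 1:10) {
    h <- kmer_enrichment(rand_seq(20, 40), rand_seq(20, 40),
                         k_min = 5, k_max = 5, n_perm = 99, min_fg_frac = 0)
    ps <- c(ps, attr(h, "all_tested")$p_perm)
  }
  expect_lte(mean(ps <= 0.05), 0.05 + 1 / 100 + 0.03)
})
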