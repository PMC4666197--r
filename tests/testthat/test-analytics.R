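make_cohort <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r)
    data.frame(individual_id = r[[1]], tissue = r[[2]], chain = r[[3]],
               cdr3_aa = r[[4]], read_count = r[[5]],
               stringsAsFactors = FALSE)))
}

test_that("tumor/normal overlap is plain set arithmetic with conserved counts", {
  cohort <- make_cohort(
    list("p1", "tumor", "beta", c("CASSA", "CASSB", "CASSC"), 2L),
    list("p1", "normal", "beta", c("CASSD", "CASSE"), 1L))
  ov <- overlap_summary(cohort)
  expect_equal(ov$summary$tumor_only, 3L)
  expect_equal(ov$summary$normal_only, 2L)
  expect_equal(ov$summary$shared, 0L)

  same <- make_cohort(
    list("p1", "tumor", "beta", c("CASSA", "CASSB"), 2L),
    list("p1", "normal", "beta", c("CASSA", "CASSB"), 3L))
  ov2 <- overlap_summary(same)
  expect_equal(ov2$summary$shared, 2L)
  expect_equal(ov2$summary$tumor_only + ov2$summary$normal_only, 0L)
  # partition: tumor_only + shared equals distinct tumor clonotypes
  mixed <- make_cohort(
    list("p1", "tumor", "beta", c("CASSA", "CASSB", "CASSC"), 2L),
    list("p1", "normal", "beta", c("CASSB", "CASSX"), 1L),
    list("p2", "tumor", "beta", c("CASSY"), 4L),
    list("p2", "normal", "beta", c("CASSY", "CASSZ"), 1L))
  ov3 <- overlap_summary(mixed)
  n_tumor <- length(unique(mixed$cdr3_aa[mixed$tissue == "tumor"]))
  expect_equal(ov3$summary$tumor_only + ov3$summary$shared, n_tumor)
  # per-CDR3 reads track tissues
  y <- ov3$per_cdr3[ov3$per_cdr3$cdr3_aa == "CASSY", ]
  expect_equal(y$reads_tumor, 4L)
  expect_equal(y$reads_normal, 1L)
  # unmatched individuals are rejected
  expect_error(overlap_summary(make_cohort(
    list("p1", "tumor", "beta", "CASSA", 1L))), "mismatched")
})

test_that("sharing profiles count individuals, reads and convergent variants", {
  cohort <- data.frame(
    individual_id = c("p1", "p2", "p2", "p3"),
    chain = "beta",
    cdr3_aa = c("CASSF", "CASSF", "CASSG", "CASSG"),
    cdr3_nt = c("TGTGCAAGCTCTTTT", "TGCGCAAGCTCTTTT", "AAA", "AAG"),
    read_count = c(2L, 3L, 1L, 5L),
    stringsAsFactors = FALSE)
  prof <- sharing_profile(cohort,
                          known = data.frame(cdr3_aa = "CASSF",
                                             specificity = "EBV"))
  f <- prof[prof$cdr3_aa == "CASSF", ]
  expect_equal(f$n_individuals, 2L)
  expect_equal(f$n_nt_variants, 2L)  # convergent recombination
  expect_equal(f$specificity, "EBV")
  expect_equal(sum(prof$total_reads), sum(cohort$read_count))
})

test_that("the pair test handles the symmetric and empty-sharing corner cases", {
  two_same <- data.frame(
    individual_id = rep(c("p1", "p2"), each = 2),
    chain = rep(c("alpha", "beta"), 2),
    cdr3_aa = rep(c("CAVR", "CASSL"), 2),
    read_count = 1L, stringsAsFactors = FALSE)
  res <- pair_cooccurrence_test(two_same, n_iterations = 50, seed = 1)
  expect_equal(res$n_observed_recurrent_pairs, 1L)
  expect_equal(res$p_value, 1)

  disjoint <- data.frame(
    individual_id = rep(c("p1", "p2"), each = 2),
    chain = rep(c("alpha", "beta"), 2),
    cdr3_aa = c("CAVA", "CASSA", "CAVB", "CASSB"),
    read_count = 1L, stringsAsFactors = FALSE)
  res2 <- pair_cooccurrence_test(disjoint, n_iterations = 50, seed = 1)
  expect_equal(res2$n_observed_recurrent_pairs, 0L)
  expect_equal(res2$p_value, 1)

  expect_error(pair_cooccurrence_test(two_same[1:2, ]), "at least 2")
})

test_that("the pair statistic ignores within-individual clonotype order and duplicates", {
  base <- data.frame(
    individual_id = rep(c("p1", "p2"), each = 4),
    chain = rep(c("alpha", "alpha", "beta", "beta"), 2),
    cdr3_aa = c("CAVA", "CAVB", "CASSA", "CASSB",
                "CAVA", "CAVB", "CASSA", "CASSB"),
    read_count = 1L, stringsAsFactors = FALSE)
  shuffled <- base[c(5:8, 4:1), ]
  shuffled$read_count <- 7L  # counts are irrelevant to the statistic
  r1 <- pair_cooccurrence_test(base, n_iterations = 20, seed = 5)
  r2 <- pair_cooccurrence_test(shuffled, n_iterations = 20, seed = 5)
  expect_equal(r1$n_observed_recurrent_pairs, 4L)
  expect_equal(r2$n_observed_recurrent_pairs, r1$n_observed_recurrent_pairs)
})

test_that("permutation p values are approximately calibrated under the null", {
  # individuals draw alpha and beta repertoires independently from shared
  # pools, so any alpha-beta co-occurrence is chance
  pvals <- null_calibration_pvals()
  expect_true(all(pvals >= 0 & pvals <= 1))
  frac <- mean(pvals <= 0.1)
  expect_gte(frac, 0.04)
  expect_lte(frac, 0.16)
})

test_that("greedy clustering matches the identity threshold semantics", {
  seqs <- data.frame(
    individual_id = c("p1", "p2"),
    cdr3_aa = c("CASSLAPGATNEKLFF", "CASSLAPGATNEKLFF"),
    stringsAsFactors = FALSE)
  cl <- cluster_cdr3(seqs)
  expect_equal(length(unique(cl$cluster_id)), 1L)
  expect_equal(nrow(cl), 2L)

  # one substitution in 16 residues: 15/16 = 93.75% < 95% -> two clusters
  variant <- data.frame(
    individual_id = c("p1", "p2"),
    cdr3_aa = c("CASSLAPGATNEKLFF", "CASSLAPGATNEKLYF"),
    stringsAsFactors = FALSE)
  cl2 <- cluster_cdr3(variant)
  expect_equal(length(unique(cl2$cluster_id)), 2L)

  # sequences of length <= 5 are discarded
  shorty <- rbind(variant, data.frame(individual_id = "p3", cdr3_aa = "CASSF"))
  expect_false("CASSF" %in% cluster_cdr3(shorty)$cdr3_aa)
})

test_that("clusters partition the retained sequences and respect the identity bound", {
  set.seed(42)
  base <- random_aa(40, c(10, 16))
  seqs <- data.frame(
    individual_id = sample(sprintf("p%d", 1:8), 120, replace = TRUE),
    cdr3_aa = c(base,
                vapply(sample(base, 80, replace = TRUE), function(s) {
                  i <- sample(nchar(s), 1)
                  substr(s, i, i) <- sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], 1)
                  s
                }, character(1))),
    stringsAsFactors = FALSE)
  cl <- cluster_cdr3(seqs)
  expect_equal(nrow(cl), nrow(seqs))           # partition (all length >= 6)
  audit <- mapply(cdr3tools:::aa_identity, cl$cdr3_aa, cl$representative)
  expect_true(all(audit >= 0.95))
  # representatives are the longest members of their clusters
  by_cl <- split(cl, cl$cluster_id)
  expect_true(all(vapply(by_cl, function(g)
    max(nchar(g$cdr3_aa)) == nchar(g$representative[1]), logical(1))))
})

test_that("the pMHC resampling test reproduces its degenerate corners", {
  clusters <- data.frame(cluster_id = c(1, 1, 2, 2, 3),
                         representative = "X",
                         individual_id = c("p1", "p2", "p1", "p3", "p2"),
                         cdr3_aa = c("CASSAAAA", "CASSAAAA", "CASSBBBB",
                                     "CASSBBBB", "CASSCCCC"),
                         stringsAsFactors = FALSE)
  universal <- data.frame(individual_id = c("p1", "p2", "p3"),
                          pmhc_id = "HLA-A0201_NLVPMVATV")
  res <- pmhc_sharing_test(clusters, universal, n_trials = 1000, seed = 1)
  expect_equal(res$raw_fraction, 1)
  expect_equal(res$adjusted_p, 1)  # capped
  expect_equal(res$n_two_individual_clusters, 2L)
  expect_equal(res$n_qualifying_clusters, 2L)

  private <- data.frame(individual_id = c("p1", "p2", "p3"),
                        pmhc_id = c("A", "B", "C"))
  res2 <- pmhc_sharing_test(clusters, private, n_trials = 1000, seed = 1)
  expect_equal(res2$n_qualifying_clusters, 0L)
  expect_equal(res2$raw_fraction, 0)
  expect_error(pmhc_sharing_test(clusters, private[0, ], 10), "empty")
})

test_that("the pMHC null fraction estimates the true pair-sharing rate", {
  # p1 and p2 share one pMHC, p3 shares with nobody: 1 of 3 pairs shares
  clusters <- data.frame(cluster_id = c(1, 1), representative = "X",
                         individual_id = c("p1", "p2"),
                         cdr3_aa = "CASSAAAA", stringsAsFactors = FALSE)
  pmhc <- data.frame(individual_id = c("p1", "p2", "p3"),
                     pmhc_id = c("S", "S", "Z"))
  res <- pmhc_sharing_test(clusters, pmhc, n_trials = 20000, seed = 2)
  expect_lt(abs(res$raw_fraction - 1 / 3), 0.02)
})
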