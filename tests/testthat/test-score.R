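test_that("wGRS equals the hand-computed weighted sum and rescales by N/n", {
  panel <- make_test_panel(c(1.5, 2.0, 1.2))
  g <- genotype_matrix(matrix(c(1, 2, 0), 1, 3,
                              dimnames = list("S1", panel$snp_id)))
  sc <- compute_wgrs(g, panel)
  expect_equal(sc$raw_sum, log(1.5) + 2 * log(2), tolerance = 1e-12)
  expect_equal(sc$scaled_score, sc$raw_sum)   # fully genotyped: no rescale
  expect_equal(sc$n_genotyped, 3L)

  # missing genotype: scaled = raw / n * N
  g2 <- genotype_matrix(matrix(c(1, NA, 2), 1, 3,
                               dimnames = list("S1", panel$snp_id)))
  sc2 <- compute_wgrs(g2, panel)
  expect_equal(sc2$raw_sum, log(1.5) + 2 * log(1.2), tolerance = 1e-12)
  expect_equal(sc2$scaled_score, sc2$raw_sum / 2 * 3, tolerance = 1e-12)

  # all-zero counts give zero score regardless of weights
  g3 <- genotype_matrix(matrix(0, 1, 3, dimnames = list("S1", panel$snp_id)))
  expect_equal(compute_wgrs(g3, panel)$scaled_score, 0)

  # the worked rescaling example: raw 5.0 at 22 of 26 SNPs -> 5/22*26
  expect_equal(5.0 / 22 * 26, 5.909091, tolerance = 1e-6)

  g4 <- genotype_matrix(matrix(NA_real_, 1, 3,
                               dimnames = list("S1", panel$snp_id)))
  expect_error(compute_wgrs(g4, panel), "zero genotyped")
})

test_that("wGRS matches a brute-force loop on random instances", {
  set.seed(101)
  for (rep in 1:50) {
    inst <- random_instance()
    sc <- compute_wgrs(inst$genotypes, inst$panel)
    for (i in seq_len(nrow(inst$genotypes))) {
      raw <- 0; n <- 0L
      for (j in seq_len(nrow(inst$panel))) {
        x <- unclass(inst$genotypes)[i, j]
        if (!is.na(x)) { raw <- raw + inst$panel$weight[j] * x; n <- n + 1L }
      }
      expect_equal(sc$raw_sum[i], raw, tolerance = 1e-12)
      expect_equal(sc$scaled_score[i], raw / n * panel_size(inst$panel),
                   tolerance = 1e-12)
    }
  }
})

test_that("doubling weights doubles scores; mean-contribution masking is neutral", {
  set.seed(5)
  inst <- random_instance()
  p2 <- inst$panel
  p2$weight <- 2 * p2$weight
  p2$or <- exp(p2$weight)
  sc1 <- compute_wgrs(inst$genotypes, inst$panel)
  sc2 <- compute_wgrs(inst$genotypes, p2)
  expect_equal(sc2$raw_sum, 2 * sc1$raw_sum, tolerance = 1e-12)
  expect_equal(sc2$scaled_score, 2 * sc1$scaled_score, tolerance = 1e-12)

  # masking SNPs whose contribution equals the sample's mean contribution
  # leaves the scaled score unchanged
  panel <- make_test_panel(c(1.5, 1.5, 1.5, 1.5))
  g <- genotype_matrix(matrix(1, 1, 4, dimnames = list("S1", panel$snp_id)))
  gm <- genotype_matrix(matrix(c(1, 1, NA, NA), 1, 4,
                               dimnames = list("S1", panel$snp_id)))
  expect_equal(compute_wgrs(gm, panel)$scaled_score,
               compute_wgrs(g, panel)$scaled_score, tolerance = 1e-12)
})

test_that("low-genotyping filter excludes exactly the under-genotyped samples", {
  panel <- make_test_panel(c(1.5, 2.0, 1.2))
  counts <- rbind(S1 = c(1, NA, NA),    # 1 genotyped -> excluded
                  S2 = c(NA, NA, 2),    # 1 genotyped -> excluded
                  S3 = c(0, 1, NA),     # 2 genotyped -> retained
                  S4 = c(1, 1, 1))      # all genotyped -> retained
  colnames(counts) <- panel$snp_id
  g <- genotype_matrix(counts)
  expect_message(res <- filter_low_genotyping(g), "excluded 2 of 4")
  expect_setequal(res$excluded, c("S1", "S2"))
  expect_equal(rownames(res$retained), c("S3", "S4"))

  # threshold generalizes: min_genotyped 3 also drops S3
  expect_message(res3 <- filter_low_genotyping(g, min_genotyped = 3),
                 "excluded 3 of 4")
  expect_equal(rownames(res3$retained), "S4")
})

test_that("categorization uses mean/SD thresholds with left-closed intervals", {
  ref <- c(4, 5, 6, 7)                  # mean 5.5, sd sqrt(5/3)
  out <- categorize_scores(c(4, 5, 6, 7), ref)
  expect_equal(out$category, 1:4)
  thr <- attr(out, "thresholds")
  expect_equal(thr, c(5.5 - sqrt(5 / 3), 5.5, 5.5 + sqrt(5 / 3)),
               tolerance = 1e-12)

  # a score exactly at the mean lands in the upper interval (category 3)
  expect_equal(categorize_scores(5.5, ref)$category, 3L)
  expect_equal(categorize_scores(thr[1], ref)$category, 2L)
  expect_equal(categorize_scores(thr[3], ref)$category, 4L)

  expect_error(categorize_scores(1, rep(2, 5)), "zero standard deviation")
  expect_error(categorize_scores(1, 2), "at least 2")
})

test_that("every score gets exactly one category and counts add up", {
  set.seed(9)
  x <- rnorm(5000, 6.3, 1.1)
  out <- categorize_scores(x)
  expect_true(all(out$category %in% 1:4))
  expect_equal(sum(table(out$category)), length(x))
})

test_that("distribution report reproduces textbook two-sample statistics", {
  rep0 <- score_distribution_report(c(1, 2, 3), c(1, 2, 3))
  expect_equal(rep0$t_stat, 0)
  expect_equal(rep0$t_p, 1)
  expect_equal(rep0$levene_stat, 0)

  rep1 <- score_distribution_report(c(1, 2, 3), c(4, 5, 6))
  expect_equal(rep1$t_stat, -3.6742, tolerance = 1e-4)
  expect_equal(rep1$t_df, 4)
  expect_equal(rep1$t_p, 0.02131164, tolerance = 1e-6)
  expect_true(rep1$pooled_variance)

  # Q-Q sample quantiles are the sorted data; theoretical axis is sorted
  qq <- rep1$qq_points
  expect_equal(qq$sample, sort(c(1, 2, 3, 4, 5, 6)))
  expect_false(is.unsorted(qq$theoretical))

  expect_error(score_distribution_report(1, c(1, 2)), "at least 2")
})

test_that("Welch form is used when variances differ (Levene p < 0.05)", {
  set.seed(21)
  a <- rnorm(200, 0, 1)
  b <- rnorm(200, 0, 5)
  rep <- score_distribution_report(a, b)
  expect_lt(rep$levene_p, 0.05)
  expect_false(rep$pooled_variance)
  tt <- t.test(a, b, var.equal = FALSE)
  expect_equal(rep$t_stat, unname(tt$statistic), tolerance = 1e-10)
  expect_equal(rep$t_df, unname(tt$parameter), tolerance = 1e-10)
})
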