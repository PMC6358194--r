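test_that("genotype simulation follows binomial moments and rejects bad freqs", {
  expect_error(simulate_genotypes(10, c(0.3, 0), seed = 1), "strictly in")
  expect_error(simulate_genotypes(10, 1.0, seed = 1), "strictly in")

  g <- simulate_genotypes(10000, 0.3, seed = 42)
  m <- mean(unclass(g))
  expect_lt(abs(m - 0.6), 3 * sqrt(2 * 0.3 * 0.7 / 10000))
  expect_false(anyNA(unclass(g)))
  # near-zero frequency: counts overwhelmingly zero
  g0 <- simulate_genotypes(2000, 1e-4, seed = 1)
  expect_gt(mean(unclass(g0) == 0), 0.999)
})

test_that("simulated genotypes sit in Hardy-Weinberg equilibrium", {
  freqs <- seq(0.1, 0.6, length.out = 10)
  n <- 2000
  pass <- 0L; total <- 0L
  for (s in 1:100) {
    g <- unclass(simulate_genotypes(n, freqs, seed = 5000 + s))
    for (j in seq_along(freqs)) {
      p <- freqs[j]
      expect_cnt <- n * c((1 - p)^2, 2 * p * (1 - p), p^2)
      obs <- tabulate(g[, j] + 1L, 3L)
      stat <- sum((obs - expect_cnt)^2 / expect_cnt)
      pass <- pass + (stats::pchisq(stat, 2, lower.tail = FALSE) >= 0.01)
      total <- total + 1L
    }
  }
  expect_gte(pass / total, 0.98)
})

test_that("simulation is deterministic under a fixed seed", {
  cfg <- simulation_config(n_cases = 200, n_controls = 100, seed = 99)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(unclass(a$genotypes), unclass(b$genotypes))
  expect_identical(as.data.frame(a$phenotypes), as.data.frame(b$phenotypes))
  # different seeds give different draws
  cfg2 <- cfg; cfg2$seed <- 100L
  c2 <- simulate_cohort(cfg2)
  expect_false(identical(unclass(a$genotypes), unclass(c2$genotypes)))
  # two-cohort wrapper forces independence under a shared seed
  pair <- simulate_two_cohorts(cfg, cfg)
  expect_false(identical(unclass(pair$a$genotypes),
                         unclass(pair$b$genotypes)))
})

test_that("cohort sizes, case-only outcomes and id scheme are honoured", {
  cfg <- simulation_config(n_cases = 150, n_controls = 70, seed = 4,
                           label = "TST")
  co <- simulate_cohort(cfg)
  ph <- as.data.frame(co$phenotypes)
  expect_equal(sum(ph$is_case == 1), 150)
  expect_equal(sum(ph$is_case == 0), 70)
  expect_true(all(grepl("^TST", ph$sample_id)))
  ctrl <- ph[ph$is_case == 0, c("family_history", "early_onset", "bilateral",
                                "ectopic", "recurrence")]
  expect_true(all(is.na(as.matrix(ctrl))))
})

test_that("missingness masking hits its rate, spares ectopic, and is MCAR", {
  cfg <- simulation_config(n_cases = 800, n_controls = 0, seed = 10,
                           genotype_missing_rate = 0,
                           phenotype_missing_rate = 0)
  co <- simulate_cohort(cfg)
  # rate 0: unchanged
  same <- apply_missingness(co, 0, 0, seed = 1)
  expect_identical(unclass(same$genotypes), unclass(co$genotypes))

  masked <- apply_missingness(co, 0.2, 0.2, seed = 2)
  frac <- mean(is.na(unclass(masked$genotypes)))
  n_cells <- length(unclass(co$genotypes))
  expect_lt(abs(frac - 0.2), 3 * sqrt(0.2 * 0.8 / n_cells))
  expect_false(anyNA(masked$phenotypes$ectopic))
  expect_gt(mean(is.na(masked$phenotypes$recurrence)), 0.1)
  # truth retains the pre-masking data
  expect_false(anyNA(unclass(masked$truth$complete_genotypes)))

  # rate 1 empties the column
  all_miss <- apply_missingness(co, 0, 1, seed = 3)
  expect_true(all(is.na(all_miss$phenotypes$sex)))
})

test_that("null generative model yields no wGRS-outcome association", {
  # gamma = 0 and beta = 0: slope CI covers 0 in most replicates
  covered <- 0L
  reps <- 60
  for (s in 1:reps) {
    at <- make_case_table(600, beta = 0, seed = 3000 + s)
    fit <- per_unit_association(at)
    est <- fit$terms[fit$terms$term == "wgrs", ]
    covered <- covered + (est$ci_low <= 1 && 1 <= est$ci_high)
  }
  expect_gte(covered / reps, 0.9)
})

test_that("recurrence prevalence increases with the generating slope", {
  at_lo <- make_case_table(4000, beta = 0, seed = 71)
  at_hi <- make_case_table(4000, beta = log(3), seed = 71)
  hi_scores <- at_hi$wgrs >= quantile(at_hi$wgrs, 0.8)
  lo_scores <- at_lo$wgrs >= quantile(at_lo$wgrs, 0.8)
  expect_gt(mean(at_hi$recurrence[hi_scores]),
            mean(at_lo$recurrence[lo_scores]))
})

test_that("complete-data wGRS looks normal for a 26-SNP panel", {
  g <- simulate_genotypes(5000, default_allele_freqs(), seed = 6,
                          snp_ids = default_panel()$snp_id)
  sc <- compute_wgrs(g, default_panel())
  # Lilliefors-style check via the installed normality test
  expect_gt(nortest::lillie.test(sc$scaled_score)$p.value, 0.01)
})

test_that("calibration hits the requested marginal prevalences", {
  cfg <- cohort_config("uk", seed = 15, n_cases = 4000, n_controls = 0)
  cfg$genotype_missing_rate <- 0
  cfg$phenotype_missing_rate <- 0
  co <- simulate_cohort(cfg)
  ph <- as.data.frame(co$phenotypes)
  cs <- ph[ph$is_case == 1, ]
  tol <- 3 * sqrt(0.25 / nrow(cs))
  expect_lt(abs(mean(cs$bilateral) - 0.63), tol + 0.02)
  expect_lt(abs(mean(cs$ectopic) - 0.10), tol + 0.02)
  expect_lt(abs(mean(cs$recurrence) - 0.30), tol + 0.02)
  expect_lt(abs(mean(ph$sex) - 0.75), tol + 0.02)
})
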