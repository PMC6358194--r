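test_that("per-unit slope transforms exactly under predictor rescaling", {
  at <- make_case_table(1500, beta = log(1.3), seed = 51)
  f1 <- per_unit_association(at)
  at2 <- at
  at2$wgrs <- at2$wgrs * 4
  f2 <- per_unit_association(at2)
  expect_equal(unname(f2$coef["wgrs"]), unname(f1$coef["wgrs"]) / 4,
               tolerance = 1e-6)
})

test_that("per-unit association recovers the generating odds ratio", {
  at <- make_case_table(20000, beta = log(1.2), seed = 52)
  fit <- per_unit_association(at)
  est <- fit$terms[fit$terms$term == "wgrs", ]
  expect_lt(abs(est$estimate - log(1.2)), 3 * est$se)
})

test_that("permuted outcomes show no association", {
  covered <- 0L
  reps <- 60
  at <- make_case_table(1000, beta = log(1.5), seed = 53)
  for (s in 1:reps) {
    perm <- at
    set.seed(s)
    perm$recurrence <- sample(perm$recurrence)
    est <- per_unit_association(perm)$terms
    est <- est[est$term == "wgrs", ]
    covered <- covered + (est$ci_low <= 1 && 1 <= est$ci_high)
  }
  expect_gte(covered / reps, 0.9)
})

test_that("category analysis: monotone generating model, null adjustment", {
  # with positive beta and no feature effects, category ORs rise with category
  at <- make_case_table(12000, beta = log(1.6), seed = 54)
  rc <- recurrence_by_category(at)
  un <- rc$unadjusted$terms
  expect_gt(un$or[un$term == "cat4"], un$or[un$term == "cat2"])
  # delta = 0: adjusted and unadjusted agree within Monte-Carlo tolerance
  ad <- rc$adjusted$terms
  for (tm in c("cat2", "cat3", "cat4")) {
    expect_lt(abs(ad$estimate[ad$term == tm] - un$estimate[un$term == tm]),
              2.5 * un$se[un$term == tm])
  }
})

test_that("category analysis errors on an empty category", {
  at <- make_case_table(200, beta = 0, seed = 55)
  at$category <- ifelse(at$wgrs > median(at$wgrs), 4L, 1L)  # 2,3 empty
  expect_error(recurrence_by_category(at), "empty score category")
})

test_that("diathesis count analysis matches closed-form 2x2 ORs", {
  # saturated indicator model: ORs equal cell ratios against count 0
  set.seed(56)
  n <- 4000
  feats <- matrix(rbinom(4 * n, 1, 0.3), n, 4)
  colnames(feats) <- c("family_history", "early_onset", "bilateral", "ectopic")
  cnt <- rowSums(feats)
  rec <- rbinom(n, 1, plogis(-1 + 0.4 * cnt))
  d <- data.frame(feats, recurrence = rec, wgrs = rnorm(n), sex = 1)
  res <- diathesis_count_analysis(d)
  tab <- res$fit$terms
  for (k in sort(unique(cnt[cnt > 0 & cnt <= 4]))) {
    a <- sum(rec == 1 & cnt == k); b <- sum(rec == 0 & cnt == k)
    c0 <- sum(rec == 1 & cnt == 0); d0 <- sum(rec == 0 & cnt == 0)
    or_closed <- (a * d0) / (b * c0)
    expect_equal(tab$or[tab$term == paste0("count", k)], or_closed,
                 tolerance = 1e-5)
  }
  # count arithmetic
  expect_equal(sum(c(1, 0, 1, 0)), 2)
})

test_that("absent count levels are flagged unavailable, not errors", {
  d <- data.frame(family_history = rep(c(0, 1), 50), early_onset = 0,
                  bilateral = 0, ectopic = 0,
                  recurrence = rbinom(100, 1, 0.4))
  res <- diathesis_count_analysis(d)
  expect_setequal(res$unavailable, 2:4)
  expect_true("count1" %in% res$fit$terms$term)
  # all features zero: no non-reference level at all
  d0 <- data.frame(family_history = 0, early_onset = 0, bilateral = 0,
                   ectopic = 0, recurrence = rbinom(50, 1, .5))
  res0 <- diathesis_count_analysis(d0)
  expect_null(res0$fit)
  expect_setequal(res0$unavailable, 1:4)
})

test_that("category-diathesis multinomial pools across an imputed stack", {
  at <- make_case_table(1200, beta = log(1.4), seed = 57,
                        delta = rep(log(1.3), 4))
  single <- category_diathesis_association(at, "bilateral")
  expect_s3_class(single, "wgrs_multifit")
  expect_named(single, c("2", "3", "4"))

  masked <- mask_mcar(at, c("wgrs", "bilateral"), 0.15, seed = 2)
  stack <- mice_impute(masked, default_mice_plan(m = 3, cycles = 3, seed = 3))
  pooled <- category_diathesis_association(stack, "bilateral")
  expect_named(pooled, c("cat2", "cat3", "cat4"))
  expect_s3_class(pooled$cat4, "pooled_estimate")
})
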