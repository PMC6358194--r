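test_that("2x2 layout reproduces the closed-form log-OR and Woolf SE", {
  # exposed: 20 events / 10 non-events; unexposed: 10 events / 20 non-events
  x <- matrix(rep(c(1, 0), each = 30), ncol = 1,
              dimnames = list(NULL, "exposed"))
  y <- c(rep(1, 20), rep(0, 10), rep(1, 10), rep(0, 20))
  fit <- fit_logistic(x, y)
  expect_true(fit$converged)
  expect_equal(unname(fit$coef["exposed"]), log(4), tolerance = 1e-6)
  se <- fit$terms$se[fit$terms$term == "exposed"]
  expect_equal(se, sqrt(1 / 20 + 1 / 10 + 1 / 10 + 1 / 20), tolerance = 1e-6)
  # balanced null: slope 0
  y0 <- c(rep(1, 15), rep(0, 15), rep(1, 15), rep(0, 15))
  expect_equal(unname(fit_logistic(x, y0)$coef["exposed"]), 0,
               tolerance = 1e-8)
})

test_that("fit matches glm coefficients and covariance on random designs", {
  set.seed(33)
  for (rep in 1:5) {
    n <- 400
    X <- cbind(a = rnorm(n), b = rbinom(n, 1, 0.4), c = runif(n))
    y <- rbinom(n, 1, plogis(-0.3 + 0.8 * X[, "a"] - 0.5 * X[, "b"]))
    fit <- fit_logistic(X, y)
    gfit <- glm(y ~ X, family = binomial(),
                control = glm.control(epsilon = 1e-12))
    expect_equal(unname(fit$coef), unname(coef(gfit)), tolerance = 1e-6)
    expect_equal(unname(fit$vcov), unname(vcov(gfit)), tolerance = 1e-5)
    expect_equal(fit$log_likelihood, as.numeric(logLik(gfit)),
                 tolerance = 1e-8)
  }
})

test_that("separation and degenerate designs raise explicit errors", {
  x <- matrix(c(rep(0, 20), rep(1, 20)), ncol = 1, dimnames = list(NULL, "z"))
  y <- c(rep(0, 20), rep(1, 20))            # complete separation
  expect_error(fit_logistic(x, y), class = "wgrs_separation_error")
  # the ridge-stabilized fit stays finite
  rfit <- fit_logistic(x, y, ridge = 1e-6)
  expect_true(all(is.finite(rfit$coef)))

  X2 <- cbind(a = rnorm(40), b = 0)          # constant column
  expect_error(fit_logistic(X2, rbinom(40, 1, .5)), "constant")
  X3 <- cbind(a = rnorm(40))
  X3 <- cbind(X3, twice = 2 * X3[, 1])       # collinear
  expect_error(fit_logistic(X3, rbinom(40, 1, .5)), "collinear")
  expect_error(fit_logistic(matrix(rnorm(10), ncol = 1), rep(2, 10)),
               "binary")
})

test_that("Wald recovery of a generating odds ratio at large n", {
  set.seed(77)
  n <- 50000
  x <- matrix(rbinom(n, 1, 0.5), ncol = 1, dimnames = list(NULL, "g"))
  y <- rbinom(n, 1, plogis(-1 + log(2) * x[, 1]))
  fit <- fit_logistic(x, y)
  est <- fit$terms[fit$terms$term == "g", ]
  expect_lt(abs(est$estimate - log(2)), 3 * est$se)
  expect_true(est$ci_low < est$or & est$or < est$ci_high)
})

test_that("adding a constant to a predictor changes only the intercept", {
  set.seed(8)
  x <- matrix(rnorm(300), ncol = 1, dimnames = list(NULL, "w"))
  y <- rbinom(300, 1, plogis(0.5 * x[, 1]))
  f1 <- fit_logistic(x, y)
  f2 <- fit_logistic(x + 10, y)
  expect_equal(unname(f2$coef["w"]), unname(f1$coef["w"]), tolerance = 1e-7)
  expect_equal(unname(f2$coef["(Intercept)"]),
               unname(f1$coef["(Intercept)"] - 10 * f1$coef["w"]),
               tolerance = 1e-6)
})

test_that("multinomial with K = 2 coincides with binary logistic", {
  set.seed(12)
  x <- matrix(rnorm(200), ncol = 1, dimnames = list(NULL, "v"))
  y <- rbinom(200, 1, plogis(0.7 * x[, 1]))
  bin <- fit_logistic(x, y)
  multi <- fit_multinomial(x, y, reference = "0")
  expect_equal(unname(multi[["1"]]$coef), unname(bin$coef), tolerance = 1e-8)
  expect_equal(unname(multi[["1"]]$vcov), unname(bin$vcov), tolerance = 1e-8)
})

test_that("saturated multinomial fit reproduces contingency-table ORs", {
  # 2x3 table: exposure x category
  tab <- rbind(c(30, 20, 10),   # unexposed counts per category
               c(15, 25, 35))   # exposed
  x <- matrix(rep(c(0, 1), rowSums(tab)), ncol = 1,
              dimnames = list(NULL, "e"))
  y <- c(rep(1:3, tab[1, ]), rep(1:3, tab[2, ]))
  fit <- fit_multinomial(x, y, reference = "1")
  for (k in 2:3) {
    or_closed <- (tab[2, k] * tab[1, 1]) / (tab[1, k] * tab[2, 1])
    expect_equal(unname(fit[[as.character(k)]]$coef["e"]), log(or_closed),
                 tolerance = 1e-6)
  }
})

test_that("multinomial agrees with nnet::multinom on random data", {
  skip_if_not_installed("nnet")
  set.seed(90)
  n <- 600
  x <- cbind(u = rnorm(n))
  lp2 <- -0.2 + 0.6 * x[, 1]; lp3 <- 0.1 - 0.4 * x[, 1]
  den <- 1 + exp(lp2) + exp(lp3)
  pr <- cbind(1 / den, exp(lp2) / den, exp(lp3) / den)
  y <- apply(pr, 1, function(p) sample(1:3, 1, prob = p))
  fit <- fit_multinomial(x, y, reference = "1")
  ref <- nnet::multinom(factor(y) ~ u, data = data.frame(u = x[, 1]),
                        trace = FALSE, reltol = 1e-14)
  co <- coef(ref)
  expect_equal(unname(fit[["2"]]$coef), unname(co["2", ]), tolerance = 1e-4)
  expect_equal(unname(fit[["3"]]$coef), unname(co["3", ]), tolerance = 1e-4)
  expect_error(fit_multinomial(x, rep(1, n)), "category")
})
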