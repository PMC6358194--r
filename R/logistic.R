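# Maximum-likelihood binary and multinomial logistic regression by Newton's
# method with step-halving.  Written against the observed information so the
# reported covariance is exactly the inverse Hessian at the optimum, and so
# that separation is surfaced as an explicit error rather than a silently
# enormous odds ratio.

MAX_NEWTON_ITER <- 50L
GRAD_TOL <- 1e-8
SEPARATION_COEF <- 15

# Numerically stable log(1 + exp(x)).
log1pexp <- function(x) ifelse(x > 0, x + log1p(exp(-x)), log1p(exp(x)))

# Build the design matrix: intercept column plus covariates.
build_design <- function(x) {
  if (is.null(x)) return(matrix(1, 0, 0))
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (is.null(colnames(x)))
    colnames(x) <- paste0("x", seq_len(ncol(x)))
  cbind("(Intercept)" = 1, x)
}

check_design <- function(X) {
  if (anyNA(X)) numeric_error("design matrix contains missing values")
  sds <- apply(X[, -1, drop = FALSE], 2, stats::sd)
  if (ncol(X) > 1 && any(sds == 0))
    numeric_error("constant non-intercept column in design")
  if (qr(X)$rank < ncol(X))
    numeric_error("collinear design matrix (rank-deficient)")
}

wald_terms <- function(coef, vcov) {
  se <- sqrt(diag(vcov))
  z <- coef / se
  data.frame(term = names(coef), estimate = unname(coef), se = unname(se),
             or = exp(unname(coef)),
             ci_low = exp(unname(coef) - Z95 * unname(se)),
             ci_high = exp(unname(coef) + Z95 * unname(se)),
             p = 2 * stats::pnorm(-abs(unname(z))),
             stringsAsFactors = FALSE)
}

#' Fit a binary logistic regression
#'
#' Maximizes the Bernoulli log-likelihood by Newton iterations with
#' step-halving, to a gradient max-norm below 1e-8 (at most 50 iterations).
#' The covariance is the inverse observed information at the optimum; odds
#' ratios and 95\% confidence intervals are Wald (z = 1.959964).  Complete or
#' quasi-complete separation raises an error rather than returning divergent
#' coefficients.
#'
#' @param x covariate matrix or data frame (without intercept; one is
#'   added), or \code{NULL} for an intercept-only model.
#' @param y binary 0/1 outcome vector.
#' @param ridge optional ridge penalty added to the Hessian diagonal
#'   (default 0; used internally to stabilize separated conditional models
#'   during imputation).
#' @return object of class \code{wgrs_fit}: list with \code{terms} (data
#'   frame term/estimate/se/or/ci_low/ci_high/p), \code{coef}, \code{vcov},
#'   \code{log_likelihood}, \code{n}, \code{n_iterations},
#'   \code{converged}.
#' @examples
#' x <- matrix(rep(c(0, 1), each = 30), ncol = 1,
#'             dimnames = list(NULL, "exposed"))
#' y <- c(rep(c(0, 1), c(20, 10)), rep(c(0, 1), c(10, 20)))
#' fit_logistic(x, y)$terms
#' @export
fit_logistic <- function(x, y, ridge = 0) {
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) numeric_error("outcome must be binary 0/1")
  X <- if (is.null(x)) matrix(1, length(y), 1,
                              dimnames = list(NULL, "(Intercept)"))
       else build_design(x)
  if (nrow(X) != length(y)) numeric_error("x and y lengths differ")
  if (ridge > 0) {
    if (anyNA(X)) numeric_error("design matrix contains missing values")
  } else {
    check_design(X)
  }
  p <- ncol(X)
  beta <- numeric(p)
  # ridge > 0 fits the ridge-penalized likelihood ll - ridge/2 * |b|^2, which
  # keeps separated conditional models finite; ridge = 0 is plain ML.
  loglik <- function(b) {
    eta <- drop(X %*% b)
    sum(y * eta - log1pexp(eta)) - ridge / 2 * sum(b^2)
  }
  ll <- loglik(beta)
  converged <- FALSE
  iter <- 0L
  grad <- NULL
  H <- NULL
  while (iter < MAX_NEWTON_ITER) {
    iter <- iter + 1L
    mu <- stats::plogis(drop(X %*% beta))
    grad <- drop(crossprod(X, y - mu)) - ridge * beta
    w <- mu * (1 - mu)
    H <- crossprod(X, X * w)
    if (ridge > 0) diag(H) <- diag(H) + ridge
    if (max(abs(grad)) < GRAD_TOL) { converged <- TRUE; break }
    if (ridge == 0 && max(abs(beta)) > SEPARATION_COEF)
      wgrs_error(paste0("complete or quasi-complete separation detected ",
                        "(|coef| > ", SEPARATION_COEF,
                        " with non-vanishing gradient)"),
                 "wgrs_separation_error")
    step <- tryCatch(solve(H, grad),
                     error = function(e)
                       numeric_error("singular information matrix in logistic fit"))
    # step-halving: never decrease the log-likelihood
    lambda <- 1
    repeat {
      cand <- beta + lambda * step
      llc <- loglik(cand)
      if (is.finite(llc) && llc >= ll - 1e-12) break
      lambda <- lambda / 2
      if (lambda < 1e-10)
        numeric_error("step-halving failed in logistic fit")
    }
    beta <- beta + lambda * step
    ll <- loglik(beta)
  }
  if (!converged) {
    mu <- stats::plogis(drop(X %*% beta))
    grad <- drop(crossprod(X, y - mu)) - ridge * beta
    if (max(abs(grad)) < GRAD_TOL) converged <- TRUE
  }
  if (!converged && ridge == 0 && max(abs(beta)) > SEPARATION_COEF)
    wgrs_error(paste0("complete or quasi-complete separation detected ",
                      "(|coef| > ", SEPARATION_COEF,
                      " with non-vanishing gradient)"),
               "wgrs_separation_error")
  if (!converged)
    numeric_error("logistic fit did not converge in 50 Newton iterations")
  vcov <- solve(H)
  dimnames(vcov) <- list(colnames(X), colnames(X))
  names(beta) <- colnames(X)
  structure(list(terms = wald_terms(beta, vcov), coef = beta, vcov = vcov,
                 log_likelihood = ll, n = length(y), n_iterations = iter,
                 converged = converged),
            class = "wgrs_fit")
}

#' @export
print.wgrs_fit <- function(x, ...) {
  cat("logistic fit: n =", x$n, "; log-likelihood =",
      format(x$log_likelihood, digits = 6), "; iterations =",
      x$n_iterations, "\n")
  print(x$terms, digits = 4, row.names = FALSE)
  invisible(x)
}

#' Fit a multinomial (softmax) logistic regression
#'
#' Maximizes the multinomial log-likelihood by Newton iterations with
#' step-halving over the full stacked coefficient vector; K-1 coefficient
#' blocks are estimated against the reference category.  With K = 2 the fit
#' coincides with \code{\link{fit_logistic}}.
#'
#' @param x covariate matrix or data frame (intercept added), or
#'   \code{NULL}.
#' @param y outcome with K >= 2 levels (factor or coercible); every level
#'   must be observed.
#' @param reference reference level (default: first sorted level; for score
#'   categories this is the lowest category).
#' @return list of class \code{wgrs_multifit}: one \code{wgrs_fit}-style
#'   element per non-reference category (named by level), plus attributes
#'   \code{reference}, \code{log_likelihood}, \code{converged}.
#' @export
fit_multinomial <- function(x, y, reference = NULL) {
  y <- factor(y)
  lev <- levels(y)
  if (any(table(y) == 0) || length(lev) < 2)
    numeric_error("every outcome category must be observed at least once")
  if (is.null(reference)) reference <- lev[1]
  reference <- as.character(reference)
  if (!reference %in% lev) numeric_error("reference level not observed")
  other <- setdiff(lev, reference)
  K1 <- length(other)
  X <- if (is.null(x)) matrix(1, length(y), 1,
                              dimnames = list(NULL, "(Intercept)"))
       else build_design(x)
  if (nrow(X) != length(y)) numeric_error("x and y lengths differ")
  check_design(X)
  p <- ncol(X)
  Y <- vapply(other, function(l) as.numeric(y == l), numeric(length(y)))
  probs <- function(Bmat) {
    eta <- X %*% Bmat                       # n x K1
    m <- pmax(0, apply(eta, 1, max))        # softmax, overflow-safe
    e <- exp(eta - m)
    e / (exp(-m) + rowSums(e))
  }
  loglik <- function(Bmat) {
    eta <- X %*% Bmat
    m <- pmax(0, apply(eta, 1, max))
    denom <- m + log(exp(-m) + rowSums(exp(eta - m)))
    sum(Y * eta) - sum(denom)
  }
  B <- matrix(0, p, K1)
  ll <- loglik(B)
  converged <- FALSE
  iter <- 0L
  Hfull <- NULL
  while (iter < MAX_NEWTON_ITER) {
    iter <- iter + 1L
    P <- probs(B)
    grad <- as.vector(crossprod(X, Y - P))  # stacked by block
    if (max(abs(grad)) < GRAD_TOL) { converged <- TRUE; break }
    if (max(abs(B)) > SEPARATION_COEF)
      wgrs_error("separation detected in multinomial fit",
                 "wgrs_separation_error")
    Hfull <- matrix(0, p * K1, p * K1)
    for (k in seq_len(K1)) for (l in seq_len(K1)) {
      w <- if (k == l) P[, k] * (1 - P[, k]) else -P[, k] * P[, l]
      Hfull[((k - 1) * p + 1):(k * p), ((l - 1) * p + 1):(l * p)] <-
        crossprod(X, X * w)
    }
    step <- tryCatch(solve(Hfull, grad),
                     error = function(e)
                       numeric_error("singular information matrix in multinomial fit"))
    lambda <- 1
    repeat {
      cand <- B + lambda * matrix(step, p, K1)
      llc <- loglik(cand)
      if (is.finite(llc) && llc >= ll - 1e-12) break
      lambda <- lambda / 2
      if (lambda < 1e-10)
        numeric_error("step-halving failed in multinomial fit")
    }
    B <- B + lambda * matrix(step, p, K1)
    ll <- loglik(B)
  }
  if (!converged && max(abs(B)) > SEPARATION_COEF)
    wgrs_error("separation detected in multinomial fit",
               "wgrs_separation_error")
  if (!converged)
    numeric_error("multinomial fit did not converge in 50 Newton iterations")
  # covariance at the optimum
  P <- probs(B)
  Hfull <- matrix(0, p * K1, p * K1)
  for (k in seq_len(K1)) for (l in seq_len(K1)) {
    w <- if (k == l) P[, k] * (1 - P[, k]) else -P[, k] * P[, l]
    Hfull[((k - 1) * p + 1):(k * p), ((l - 1) * p + 1):(l * p)] <-
      crossprod(X, X * w)
  }
  V <- solve(Hfull)
  fits <- stats::setNames(vector("list", K1), other)
  for (k in seq_len(K1)) {
    idx <- ((k - 1) * p + 1):(k * p)
    ck <- stats::setNames(B[, k], colnames(X))
    vk <- V[idx, idx, drop = FALSE]
    dimnames(vk) <- list(colnames(X), colnames(X))
    fits[[k]] <- structure(list(terms = wald_terms(ck, vk), coef = ck,
                                vcov = vk, log_likelihood = ll,
                                n = length(y), n_iterations = iter,
                                converged = converged),
                           class = "wgrs_fit")
  }
  structure(fits, class = "wgrs_multifit", reference = reference,
            log_likelihood = ll, converged = converged)
}
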