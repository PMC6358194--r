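# Multiple imputation by chained equations over the analysis variables
# (recurrence, wGRS, the diathesis features, sex), plus Rubin's-rules
# pooling of regression estimates across completed datasets.

#' Build a chained-equations imputation plan
#'
#' @param variables data frame with columns \code{name}, \code{kind}
#'   (\code{"binary"} or \code{"continuous"}) and \code{imputed} (logical).
#'   Non-imputed variables still enter every conditional model as
#'   predictors.
#' @param m number of imputed datasets (default 75).
#' @param cycles chained-equation sweeps per dataset (default 100).
#' @param seed master seed; each of the m chains gets an independent
#'   substream.
#' @return list of class \code{mice_plan}.
#' @export
mice_plan <- function(variables, m = 75L, cycles = 100L, seed = 1L) {
  need <- c("name", "kind", "imputed")
  if (!all(need %in% names(variables)))
    config_error("variables must have columns name, kind, imputed")
  if (!all(variables$kind %in% c("binary", "continuous")))
    config_error("variable kind must be 'binary' or 'continuous'")
  if (!any(variables$imputed))
    config_error("at least one variable must be imputed")
  if (m < 2L) config_error("m must be >= 2 for pooling")
  if (cycles < 1L) config_error("cycles must be >= 1")
  structure(list(variables = variables, m = as.integer(m),
                 cycles = as.integer(cycles), seed = as.integer(seed)),
            class = "mice_plan")
}

#' Default imputation plan for the recurrence analysis
#'
#' The chain covers recurrence, wGRS, family history, early onset, ectopic
#' disease, bilateral disease and sex.  By default ectopic disease enters
#' the conditional models but is not itself imputed (it is observed without
#' missingness in the larger cohort); set \code{impute_ectopic = TRUE} for
#' cohorts where it has missing values.
#'
#' @param impute_ectopic logical.
#' @param m,cycles,seed see \code{\link{mice_plan}}.
#' @return a \code{mice_plan}.
#' @export
default_mice_plan <- function(impute_ectopic = FALSE, m = 75L, cycles = 100L,
                              seed = 1L) {
  vars <- data.frame(
    name = c("recurrence", "wgrs", "family_history", "early_onset",
             "ectopic", "bilateral", "sex"),
    kind = c("binary", "continuous", "binary", "binary", "binary", "binary",
             "binary"),
    imputed = c(TRUE, TRUE, TRUE, TRUE, impute_ectopic, TRUE, TRUE),
    stringsAsFactors = FALSE)
  mice_plan(vars, m = m, cycles = cycles, seed = seed)
}

# Conditional-model draws -----------------------------------------------

# Binary conditional: logistic fit on observed rows, coefficients perturbed
# by a draw from their asymptotic normal, then a Bernoulli draw.  Falls back
# to a ridge-stabilized fit (penalty 1e-6) when the unpenalized fit fails,
# e.g. under separation.
draw_binary <- function(X_obs, y_obs, X_mis) {
  fit <- tryCatch(fit_logistic(X_obs, y_obs),
                  wgrs_error = function(e) {
                    message("chained-equations: ridge-stabilized logistic fallback (",
                            conditionMessage(e), ")")
                    fit_logistic(X_obs, y_obs, ridge = 1e-6)
                  })
  beta_star <- MASS::mvrnorm(1, fit$coef, fit$vcov)
  p <- stats::plogis(drop(cbind(1, X_mis) %*% beta_star))
  stats::rbinom(length(p), 1L, p)
}

# Continuous conditional: normal linear model with posterior draws of the
# residual variance (scaled inverse chi-square) and coefficients, plus
# residual noise on the predictions (Bayesian linear regression imputation).
draw_continuous <- function(X_obs, y_obs, X_mis) {
  X <- cbind(1, X_obs)
  XtX <- crossprod(X)
  d <- ncol(X)
  ridge <- 0
  V <- tryCatch(solve(XtX), error = function(e) {
    ridge <<- 1e-6 * mean(diag(XtX))
    solve(XtX + diag(ridge, d))
  })
  beta <- drop(V %*% crossprod(X, y_obs))
  res <- y_obs - drop(X %*% beta)
  df <- max(length(y_obs) - d, 1L)
  sigma2 <- sum(res^2) / stats::rchisq(1, df)
  beta_star <- beta + drop(t(chol((V + t(V)) / 2)) %*% stats::rnorm(d)) *
    sqrt(sigma2)
  drop(cbind(1, X_mis) %*% beta_star) +
    stats::rnorm(nrow(X_mis), 0, sqrt(sigma2))
}

#' Multiple imputation by chained equations
#'
#' Produces \code{m} completed copies of \code{data}.  Each chain is
#' initialized by random draws from every variable's observed values, then
#' swept \code{cycles} times in fixed visit order (ascending missingness
#' rate, ties in plan order).  Binary variables are imputed by logistic
#' posterior-draw models, the continuous wGRS by a normal linear model with
#' posterior-draw coefficients and residual noise.  Chains use independent
#' seed substreams; non-imputed cells are never altered.
#'
#' @param data data frame containing every plan variable (extra columns such
#'   as \code{sample_id} are carried through untouched).
#' @param plan a \code{\link{mice_plan}}.
#' @return list of class \code{imputed_stack}: \code{datasets} (list of m
#'   completed data frames), \code{plan}, \code{chain_seeds}, and
#'   \code{diagnostics} (per chain x cycle x variable mean of imputed
#'   values).
#' @export
mice_impute <- function(data, plan) {
  stopifnot(inherits(plan, "mice_plan"))
  vars <- plan$variables
  miss_cols <- setdiff(vars$name, names(data))
  if (length(miss_cols))
    config_error(paste("data lacks plan variable(s):",
                       paste(miss_cols, collapse = ", ")))
  for (v in vars$name)
    if (all(is.na(data[[v]])))
      numeric_error(paste0("variable '", v, "' has no observed values"))
  miss_rate <- vapply(vars$name, function(v) mean(is.na(data[[v]])),
                      numeric(1))
  to_impute <- vars$name[vars$imputed & miss_rate[vars$name] > 0]
  not_imputed <- vars$name[!vars$imputed]
  if (any(miss_rate[not_imputed] > 0))
    config_error(paste("non-imputed variable(s) contain missing values:",
                       paste(not_imputed[miss_rate[not_imputed] > 0],
                             collapse = ", ")))
  chain_seeds <- derive_seeds(plan$seed, paste0("chain", seq_len(plan$m)))
  if (!length(to_impute)) {
    return(structure(list(datasets = rep(list(data), plan$m), plan = plan,
                          chain_seeds = chain_seeds, diagnostics = NULL),
                     class = "imputed_stack"))
  }
  # visit order: ascending missingness, ties broken by plan order
  visit <- to_impute[order(miss_rate[to_impute],
                           match(to_impute, vars$name))]
  kind <- stats::setNames(vars$kind, vars$name)
  was_missing <- lapply(stats::setNames(vars$name, vars$name),
                        function(v) is.na(data[[v]]))
  datasets <- vector("list", plan$m)
  diag_arr <- array(NA_real_, c(plan$m, plan$cycles, length(visit)),
                    dimnames = list(NULL, NULL, visit))
  for (j in seq_len(plan$m)) {
    datasets[[j]] <- with_seed(chain_seeds[j], {
      d <- data
      for (v in visit) {
        mis <- was_missing[[v]]
        obs_vals <- d[[v]][!mis]
        d[[v]][mis] <- sample(obs_vals, sum(mis), replace = TRUE)
      }
      for (cyc in seq_len(plan$cycles)) {
        for (v in visit) {
          mis <- was_missing[[v]]
          preds <- setdiff(vars$name, v)
          Xall <- as.matrix(d[preds])
          X_obs <- Xall[!mis, , drop = FALSE]
          X_mis <- Xall[mis, , drop = FALSE]
          y_obs <- d[[v]][!mis]
          d[[v]][mis] <- if (kind[[v]] == "binary")
            draw_binary(X_obs, y_obs, X_mis)
          else draw_continuous(X_obs, y_obs, X_mis)
          diag_arr[j, cyc, v] <- mean(d[[v]][mis])
        }
      }
      d
    })
  }
  structure(list(datasets = datasets, plan = plan,
                 chain_seeds = chain_seeds, diagnostics = diag_arr),
            class = "imputed_stack")
}

#' @export
print.imputed_stack <- function(x, ...) {
  cat("imputed stack: m =", length(x$datasets), "datasets,",
      x$plan$cycles, "cycles,", nrow(x$datasets[[1]]), "rows\n")
  invisible(x)
}

#' Pool estimates across imputed datasets by Rubin's rules
#'
#' For each coefficient, the pooled estimate is the mean over the m
#' per-dataset estimates; total variance is the mean within-imputation
#' variance plus \eqn{(1 + 1/m)} times the between-imputation variance
#' (sample variance, n-1 denominator).  Confidence intervals and p-values
#' use a t distribution with Barnard-Rubin adjusted degrees of freedom.
#'
#' @param fits list of m fits: \code{wgrs_fit} objects, or lists with
#'   elements \code{coef} and \code{vcov} (or \code{se}).  All fits must
#'   share the same coefficient layout.
#' @param nu_com complete-data degrees of freedom for the Barnard-Rubin
#'   adjustment; defaults to n - p from the first fit when available, else
#'   \code{Inf} (which reduces to the classical large-sample df).
#' @return data frame of class \code{pooled_estimate} with columns
#'   \code{term}, \code{q_bar}, \code{w_bar}, \code{b}, \code{total_var},
#'   \code{se}, \code{df}, \code{ci_low}, \code{ci_high} (coefficient
#'   scale), \code{or}, \code{or_low}, \code{or_high}, \code{p}.
#' @export
pool_rubin <- function(fits, nu_com = NULL) {
  m <- length(fits)
  if (m < 2L) config_error("pooling requires m >= 2 fits")
  get_coef <- function(f) if (!is.null(f$coef)) f$coef else
    stop("fit lacks coefficients")
  get_var <- function(f) {
    if (!is.null(f$vcov)) diag(as.matrix(f$vcov))
    else if (!is.null(f$se)) f$se^2
    else stop("fit lacks variances")
  }
  cn <- names(get_coef(fits[[1]]))
  Q <- t(vapply(fits, get_coef, numeric(length(cn))))
  U <- t(vapply(fits, get_var, numeric(length(cn))))
  if (length(cn) == 1L) { Q <- t(Q); U <- t(U) }
  for (f in fits)
    if (!identical(names(get_coef(f)), cn))
      config_error("inconsistent coefficient layouts across fits")
  if (is.null(nu_com))
    nu_com <- if (!is.null(fits[[1]]$n)) fits[[1]]$n - length(cn) else Inf
  q_bar <- colMeans(Q)
  w_bar <- colMeans(U)
  b <- apply(Q, 2, stats::var)
  total <- w_bar + (1 + 1 / m) * b
  lambda <- (1 + 1 / m) * b / total
  df <- ifelse(lambda <= 0, Inf, {
    df_old <- (m - 1) / pmax(lambda, 1e-300)^2
    if (is.finite(nu_com)) {
      df_obs <- (nu_com + 1) / (nu_com + 3) * nu_com * (1 - lambda)
      df_old * df_obs / (df_old + df_obs)
    } else df_old
  })
  se <- sqrt(total)
  tcrit <- ifelse(is.finite(df), stats::qt(0.975, df), stats::qnorm(0.975))
  p <- 2 * ifelse(is.finite(df), stats::pt(-abs(q_bar / se), df),
                  stats::pnorm(-abs(q_bar / se)))
  out <- data.frame(term = cn, q_bar = unname(q_bar), w_bar = unname(w_bar),
                    b = unname(b), total_var = unname(total),
                    se = unname(se), df = unname(df),
                    ci_low = unname(q_bar - tcrit * se),
                    ci_high = unname(q_bar + tcrit * se),
                    or = exp(unname(q_bar)),
                    or_low = exp(unname(q_bar - tcrit * se)),
                    or_high = exp(unname(q_bar + tcrit * se)),
                    p = unname(p), stringsAsFactors = FALSE)
  structure(out, class = c("pooled_estimate", "data.frame"), m = m,
            nu_com = nu_com)
}
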