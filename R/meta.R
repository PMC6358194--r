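# Fixed-effect inverse-variance meta-analysis of per-cohort log odds
# ratios, with helpers to recover a study estimate from a published OR and
# 95% confidence interval.

#' Study estimate on the log odds-ratio scale
#' @param label study label.
#' @param log_or log odds ratio.
#' @param se standard error of the log odds ratio (> 0).
#' @return data frame row of class \code{study_estimate}.
#' @export
study_estimate <- function(label, log_or, se) {
  if (any(se <= 0) || any(!is.finite(se)))
    numeric_error("study standard errors must be finite and > 0")
  structure(data.frame(label = as.character(label), log_or = log_or, se = se,
                       stringsAsFactors = FALSE),
            class = c("study_estimate", "data.frame"))
}

#' Recover a study estimate from an odds ratio and 95\% CI
#'
#' Back-transforms a published OR with Wald 95\% confidence interval:
#' \code{log_or = log(or)} and \code{se = (log(ci_high) - log(ci_low)) /
#' (2 * 1.959964)}.  A warning is raised when the log-scale interval is
#' asymmetric about the log OR by more than 2\% of its half-width,
#' indicating the interval was probably not Wald.
#'
#' @param label study label.
#' @param or_value odds ratio (> 0).
#' @param ci_low,ci_high 95\% confidence bounds with
#'   \code{ci_low < or_value < ci_high}.
#' @return a \code{\link{study_estimate}}.
#' @examples
#' se_from_ci("uk", 1.18, 1.06, 1.31)
#' @export
se_from_ci <- function(label, or_value, ci_low, ci_high) {
  if (!(ci_low < or_value && or_value < ci_high))
    numeric_error("requires ci_low < or < ci_high")
  if (ci_low <= 0) numeric_error("confidence bounds must be positive")
  log_or <- log(or_value)
  half <- (log(ci_high) - log(ci_low)) / 2
  mid <- (log(ci_high) + log(ci_low)) / 2
  if (abs(mid - log_or) > 0.02 * half)
    warning("confidence interval asymmetric about log(OR) beyond 2%: ",
            "Wald back-transform may be inaccurate")
  study_estimate(label, log_or, half / Z95)
}

#' Fixed-effect inverse-variance meta-analysis
#'
#' Pools study log odds ratios with weights \eqn{w_i = 1/se_i^2}:
#' pooled log OR \eqn{= \sum w_i \hat\theta_i / \sum w_i}, pooled SE
#' \eqn{= (\sum w_i)^{-1/2}}, Wald 95\% CI on the OR scale and two-sided
#' normal p-value.  Cochran's Q and I\eqn{^2} are reported as descriptive
#' heterogeneity statistics only; the pooling model is always fixed-effect.
#'
#' @param studies a \code{\link{study_estimate}} data frame (>= 1 row).
#' @return list of class \code{meta_result}: \code{pooled_log_or},
#'   \code{pooled_se}, \code{pooled_or}, \code{ci_low}, \code{ci_high} (OR
#'   scale), \code{z}, \code{p}, \code{weights} (normalized, sum 1),
#'   \code{q}, \code{q_df}, \code{q_p}, \code{i2}, \code{studies}.
#' @examples
#' s <- rbind(study_estimate("a", 0.1, 0.1), study_estimate("b", 0.3, 0.2))
#' fixed_effect_meta(s)
#' @export
fixed_effect_meta <- function(studies) {
  if (!nrow(studies)) numeric_error("no studies to pool")
  if (any(studies$se <= 0)) numeric_error("study se must be > 0")
  w <- 1 / studies$se^2
  pooled <- sum(w * studies$log_or) / sum(w)
  pooled_se <- 1 / sqrt(sum(w))
  z <- pooled / pooled_se
  q <- sum(w * (studies$log_or - pooled)^2)
  q_df <- nrow(studies) - 1L
  structure(list(pooled_log_or = pooled, pooled_se = pooled_se,
                 pooled_or = exp(pooled),
                 ci_low = exp(pooled - Z95 * pooled_se),
                 ci_high = exp(pooled + Z95 * pooled_se),
                 z = z, p = 2 * stats::pnorm(-abs(z)),
                 weights = stats::setNames(w / sum(w), studies$label),
                 q = q, q_df = q_df,
                 q_p = if (q_df > 0) stats::pchisq(q, q_df, lower.tail = FALSE)
                       else NA_real_,
                 i2 = if (q_df > 0) max(0, (q - q_df) / q) else NA_real_,
                 studies = studies),
            class = "meta_result")
}

#' @export
print.meta_result <- function(x, ...) {
  cat(sprintf("fixed-effect meta-analysis of %d studies\n",
              nrow(x$studies)))
  cat(sprintf("pooled OR %.4f (95%% CI %.4f-%.4f), z = %.3f, p = %.3g\n",
              x$pooled_or, x$ci_low, x$ci_high, x$z, x$p))
  cat(sprintf("heterogeneity: Q = %.3f (df %d), I2 = %s\n", x$q, x$q_df,
              if (is.na(x$i2)) "NA" else sprintf("%.1f%%", 100 * x$i2)))
  invisible(x)
}

#' Read study estimates from TSV
#'
#' Accepts either columns \code{label}, \code{log_or}, \code{se} or columns
#' \code{label}, \code{or}, \code{ci_low}, \code{ci_high} (back-transformed
#' via \code{\link{se_from_ci}}).
#'
#' @param path TSV path.
#' @return a \code{\link{study_estimate}} data frame.
#' @export
read_study_estimates <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (all(c("log_or", "se") %in% names(df)))
    return(study_estimate(df$label, df$log_or, df$se))
  if (all(c("or", "ci_low", "ci_high") %in% names(df))) {
    rows <- lapply(seq_len(nrow(df)), function(i)
      se_from_ci(df$label[i], df$or[i], df$ci_low[i], df$ci_high[i]))
    return(do.call(rbind, rows))
  }
  format_error("study TSV needs columns (label, log_or, se) or (label, or, ci_low, ci_high)")
}

#' Write a meta-analysis result as TSV
#' @param meta a \code{meta_result}.
#' @param path output path.
#' @export
write_meta <- function(meta, path) {
  out <- data.frame(pooled_or = meta$pooled_or,
                    pooled_log_or = meta$pooled_log_or,
                    pooled_se = meta$pooled_se,
                    ci_low = meta$ci_low, ci_high = meta$ci_high,
                    z = meta$z, p = meta$p, q = meta$q, q_df = meta$q_df,
                    i2 = meta$i2)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
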