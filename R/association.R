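# Case-only association analyses: per-unit wGRS effects, score-category
# effects, diathesis-count effects, and the multinomial association between
# score category and each diathesis feature.  Every analysis runs either on
# a single completed data frame or on an imputed stack (fit per dataset,
# then Rubin-pooled).

#' Assemble the case-only analysis table
#'
#' Joins scaled wGRS values onto the phenotype table and restricts to cases.
#' Samples present in the phenotypes but absent from the scores get a
#' missing wGRS (to be imputed).
#'
#' @param phenotypes a \code{\link{phenotype_table}}.
#' @param scores a \code{score_result} from \code{\link{compute_wgrs}}.
#' @param cases_only drop controls (default TRUE; the recurrence and
#'   diathesis outcomes are defined for cases only).
#' @return data frame with \code{sample_id}, \code{sex}, the four diathesis
#'   features, \code{recurrence} and \code{wgrs}.
#' @export
analysis_table <- function(phenotypes, scores, cases_only = TRUE) {
  df <- as.data.frame(phenotypes)
  df$wgrs <- scores$scaled_score[match(df$sample_id, scores$sample_id)]
  if (cases_only) df <- df[!is.na(df$is_case) & df$is_case == 1, ]
  rownames(df) <- NULL
  cols <- c("sample_id", "sex", DIATHESIS_FEATURES, "recurrence", "wgrs")
  if (!cases_only) cols <- c(cols, "is_case")
  df[cols]
}

# Apply a fitting function across an imputed stack and Rubin-pool, or fit
# once on a plain data frame.
fit_or_pool <- function(data, fit_fun) {
  if (inherits(data, "imputed_stack")) {
    fits <- lapply(data$datasets, fit_fun)
    pool_rubin(fits)
  } else fit_fun(data)
}

#' Per-unit wGRS association
#'
#' Logistic regression of a binary outcome on the continuous wGRS,
#' optionally adjusted for diathesis features: the per-unit odds ratio is
#' \code{exp} of the wGRS coefficient.
#'
#' @param data completed data frame (from \code{\link{analysis_table}}) or
#'   an \code{imputed_stack} of such frames.
#' @param outcome outcome column name (default \code{"recurrence"}).
#' @param adjust character vector of adjustment columns (default none).
#' @return a \code{wgrs_fit}, or a \code{pooled_estimate} for a stack.
#' @export
per_unit_association <- function(data, outcome = "recurrence",
                                 adjust = character()) {
  fit_or_pool(data, function(d) {
    keep <- stats::complete.cases(d[c(outcome, "wgrs", adjust)])
    d <- d[keep, , drop = FALSE]
    fit_logistic(as.matrix(d[c("wgrs", adjust)]), d[[outcome]])
  })
}

# Assign score categories within one completed dataset (reference: its own
# scores, i.e. the cases of the same cohort).
add_category_column <- function(d, reference = NULL) {
  d$category <- categorize_scores(d$wgrs,
                                  if (is.null(reference)) d$wgrs else reference)$category
  d
}

#' Recurrence by wGRS category
#'
#' Logistic regression of recurrence on indicators for score categories 2-4
#' (category 1, the lowest, is the reference), unadjusted and adjusted for
#' the four diathesis features.  On an imputed stack, categories are
#' re-derived within each completed dataset from its (partly imputed) wGRS
#' values, the model is fitted per dataset, and estimates are Rubin-pooled.
#'
#' @param data completed case-only data frame or \code{imputed_stack}; must
#'   contain \code{wgrs} (or a pre-assigned \code{category} column) and
#'   \code{recurrence}.
#' @param adjust adjustment columns (default: the four diathesis features).
#' @param reference_scores optional numeric vector from which category
#'   thresholds are computed (default: the data's own scores).
#' @return list with elements \code{unadjusted} and \code{adjusted}, each a
#'   \code{wgrs_fit} or \code{pooled_estimate} with terms \code{cat2},
#'   \code{cat3}, \code{cat4} (and the adjustment terms).
#' @export
recurrence_by_category <- function(data, adjust = DIATHESIS_FEATURES,
                                   reference_scores = NULL) {
  one <- function(d, adj) {
    if (is.null(d$category)) d <- add_category_column(d, reference_scores)
    keep <- stats::complete.cases(d[c("recurrence", "category", adj)])
    d <- d[keep, , drop = FALSE]
    present <- sort(unique(d$category))
    if (!all(1:4 %in% present))
      numeric_error(paste("empty score category after case filtering:",
                          paste(setdiff(1:4, present), collapse = ", ")))
    X <- cbind(cat2 = as.numeric(d$category == 2),
               cat3 = as.numeric(d$category == 3),
               cat4 = as.numeric(d$category == 4))
    if (length(adj)) X <- cbind(X, as.matrix(d[adj]))
    fit_logistic(X, d$recurrence)
  }
  list(unadjusted = fit_or_pool(data, function(d) one(d, character())),
       adjusted = fit_or_pool(data, function(d) one(d, adjust)))
}

#' Odds of recurrence by number of diathesis features
#'
#' The diathesis count is the sum of the four binary features (0-4); the
#' model regresses recurrence on indicators for counts 1-4 against count 0.
#' Count levels absent from the data — or without outcome variation, where
#' the cell odds ratio is not finite — are flagged unavailable rather than
#' raising an error.
#'
#' @param data completed case-only data frame or \code{imputed_stack} with
#'   the four diathesis features and \code{recurrence}.
#' @return list with \code{fit} (a \code{wgrs_fit} or
#'   \code{pooled_estimate}; terms \code{count1}..\code{count4} for
#'   available levels) and \code{unavailable} (integer vector of absent
#'   count levels).
#' @export
diathesis_count_analysis <- function(data) {
  count_of <- function(d) rowSums(d[DIATHESIS_FEATURES])
  # a level is usable only when its cell OR is finite, i.e. it holds both
  # events and non-events in every completed dataset
  lev_in <- function(d) {
    keep <- stats::complete.cases(d[c("recurrence", DIATHESIS_FEATURES)])
    d <- d[keep, , drop = FALSE]
    cnt <- count_of(d)
    ks <- sort(unique(cnt))
    ks[vapply(ks, function(k) {
      r <- d$recurrence[cnt == k]
      any(r == 1) && any(r == 0)
    }, logical(1))]
  }
  levels_present <- if (inherits(data, "imputed_stack"))
    Reduce(intersect, lapply(data$datasets, lev_in)) else lev_in(data)
  if (!0 %in% levels_present)
    numeric_error("reference level (zero diathesis features) empty or without outcome variation")
  use <- setdiff(levels_present, 0)
  unavailable <- setdiff(1:4, use)
  if (!length(use))
    return(list(fit = NULL, unavailable = unavailable))
  one <- function(d) {
    keep <- stats::complete.cases(d[c("recurrence", DIATHESIS_FEATURES)])
    d <- d[keep, , drop = FALSE]
    cnt <- count_of(d)
    d <- d[cnt %in% c(0, use), , drop = FALSE]
    cnt <- cnt[cnt %in% c(0, use)]
    X <- vapply(use, function(k) as.numeric(cnt == k), numeric(length(cnt)))
    colnames(X) <- paste0("count", use)
    fit_logistic(X, d$recurrence)
  }
  list(fit = fit_or_pool(data, one), unavailable = unavailable)
}

#' Association between score category and a diathesis feature
#'
#' Multinomial logistic regression of the four-level score category (outcome,
#' reference: the lowest category) on one diathesis feature, fitted per
#' feature (univariable).
#'
#' @param data completed case-only data frame or \code{imputed_stack}.
#' @param feature one diathesis feature column name.
#' @param reference_scores optional thresholds reference (see
#'   \code{\link{recurrence_by_category}}).
#' @return for a data frame, a \code{wgrs_multifit}; for a stack, a named
#'   list (categories 2-4) of \code{pooled_estimate}s.
#' @export
category_diathesis_association <- function(data, feature,
                                           reference_scores = NULL) {
  one <- function(d) {
    if (is.null(d$category)) d <- add_category_column(d, reference_scores)
    keep <- stats::complete.cases(d[c("category", feature)])
    d <- d[keep, , drop = FALSE]
    fit_multinomial(as.matrix(d[feature]), d$category, reference = "1")
  }
  if (!inherits(data, "imputed_stack")) return(one(data))
  multis <- lapply(data$datasets, one)
  cats <- names(multis[[1]])
  out <- lapply(stats::setNames(cats, paste0("cat", cats)), function(k)
    pool_rubin(lapply(multis, `[[`, k)))
  out
}

#' Write a fit or pooled estimate as TSV
#' @param fit a \code{wgrs_fit} or \code{pooled_estimate}.
#' @param path output path.
#' @export
write_fit <- function(fit, path) {
  tab <- if (inherits(fit, "wgrs_fit")) cbind(fit$terms, n = fit$n,
                                              converged = fit$converged)
         else as.data.frame(fit)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
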