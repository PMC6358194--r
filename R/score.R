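# Core weighted genetic risk score computation, the low-genotyping
# exclusion, the mean/SD categorization and the distributional report.

#' Compute weighted genetic risk scores
#'
#' For each sample the raw score is \eqn{\sum_i W_i X_i} over the SNPs
#' genotyped for that sample, where \eqn{W_i = \log OR_i} is the panel
#' weight and \eqn{X_i \in \{0,1,2\}} the effect-allele count.  To keep
#' samples with missing genotypes comparable, the raw sum is divided by the
#' number of SNPs genotyped for the sample (\eqn{n}) and multiplied by the
#' panel size \eqn{N} (26 for the shipped panel):
#' \deqn{wGRS = \frac{N}{n} \sum_{i \in genotyped} W_i X_i.}
#'
#' @param genotypes a \code{\link{genotype_matrix}} (or a named numeric
#'   vector of counts for a single sample) whose SNP columns match the panel.
#' @param panel a \code{\link{weight_panel}}.
#' @return data frame of class \code{score_result} with columns
#'   \code{sample_id}, \code{raw_sum}, \code{n_genotyped},
#'   \code{scaled_score}.
#' @examples
#' p <- weight_panel(c("a","b","c"), "1", 1:3, "A", "G", c(1.5, 2, 1.2))
#' g <- genotype_matrix(matrix(c(1, 2, 0), 1, 3,
#'                      dimnames = list("S1", c("a","b","c"))))
#' compute_wgrs(g, p)
#' @export
compute_wgrs <- function(genotypes, panel) {
  stopifnot(inherits(panel, "weight_panel"))
  if (is.null(dim(genotypes))) {
    genotypes <- matrix(genotypes, nrow = 1,
                        dimnames = list("sample", names(genotypes)))
  }
  if (!identical(colnames(genotypes), panel$snp_id))
    format_error("genotype columns do not match the panel's SNPs")
  x <- unclass(genotypes)
  n_geno <- rowSums(!is.na(x))
  if (any(n_geno == 0))
    numeric_error(paste0("score undefined: sample(s) with zero genotyped SNPs: ",
                         paste(rownames(x)[n_geno == 0], collapse = ", ")))
  contrib <- sweep(x, 2, panel$weight, `*`)
  raw <- rowSums(contrib, na.rm = TRUE)
  out <- data.frame(sample_id = rownames(x),
                    raw_sum = raw,
                    n_genotyped = as.integer(n_geno),
                    scaled_score = raw / n_geno * panel_size(panel),
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(out, class = c("score_result", "data.frame"))
}

#' Exclude samples genotyped at too few SNPs
#'
#' Samples genotyped at fewer than \code{min_genotyped} panel SNPs carry too
#' little information for the missing-at-random rescaling to be defensible
#' and are removed before scoring and imputation.  The default of 2
#' generalizes the exclusion of samples genotyped at a single SNP.
#'
#' @param genotypes a \code{\link{genotype_matrix}}.
#' @param min_genotyped minimum number of non-missing genotypes to retain a
#'   sample (default 2).
#' @return list with \code{retained} (a \code{genotype_matrix}) and
#'   \code{excluded} (character vector of removed sample ids).  The number
#'   excluded is reported via \code{message()}.
#' @export
filter_low_genotyping <- function(genotypes, min_genotyped = 2L) {
  stopifnot(min_genotyped >= 1L)
  n_geno <- rowSums(!is.na(unclass(genotypes)))
  drop <- n_geno < min_genotyped
  message("filter_low_genotyping: excluded ", sum(drop), " of ",
          length(drop), " samples genotyped at fewer than ",
          min_genotyped, " SNPs")
  list(retained = genotypes[!drop, , drop = FALSE],
       excluded = rownames(genotypes)[drop])
}

#' @export
`[.genotype_matrix` <- function(x, i, j, ..., drop = FALSE) {
  out <- NextMethod(drop = drop)
  if (is.matrix(out)) class(out) <- c("genotype_matrix", class(out))
  out
}

#' Categorize scores on mean and standard-deviation thresholds
#'
#' Scores are divided into four groups using the reference population's
#' mean − 1 SD, mean, and mean + 1 SD as thresholds (sample SD, \eqn{n-1}
#' denominator).  Intervals are left-closed on the upper side:
#' \eqn{(-\infty, m-s)}, \eqn{[m-s, m)}, \eqn{[m, m+s)},
#' \eqn{[m+s, \infty)}, mapping to categories 1-4, so a score exactly at a
#' threshold falls in the upper interval.
#'
#' @param scores a \code{score_result} data frame or numeric vector of
#'   scaled scores.
#' @param reference_scores numeric vector from which thresholds are
#'   computed; defaults to the scores themselves.  Must have length >= 2 and
#'   positive SD.
#' @return data frame with columns \code{sample_id} (when available) and
#'   \code{category} (integer 1-4), plus attribute \code{thresholds}.
#' @export
categorize_scores <- function(scores, reference_scores = NULL) {
  if (inherits(scores, "score_result")) {
    ids <- scores$sample_id
    x <- scores$scaled_score
  } else {
    ids <- names(scores)
    x <- as.numeric(scores)
  }
  if (is.null(reference_scores)) reference_scores <- x
  if (length(reference_scores) < 2)
    numeric_error("need at least 2 reference scores for thresholds")
  m <- mean(reference_scores)
  s <- stats::sd(reference_scores)
  if (!is.finite(s) || s <= 0)
    numeric_error("reference scores have zero standard deviation")
  thr <- c(m - s, m, m + s)
  category <- as.integer(findInterval(x, thr) + 1L)  # left-closed
  out <- data.frame(sample_id = if (is.null(ids)) seq_along(x) else ids,
                    category = category, stringsAsFactors = FALSE)
  attr(out, "thresholds") <- thr
  out
}

#' Distributional comparison of two score groups
#'
#' Compares wGRS distributions between two groups (cases vs controls, or
#' women vs men): the mean-centered Levene test for equality of variances,
#' a two-tailed two-sample t test (pooled variance when the Levene p-value
#' is >= 0.05, Welch otherwise), and normal Q-Q coordinates of the combined
#' sample against a normal with matching mean and SD, for external plotting.
#'
#' @param group_a,group_b numeric vectors, each of length >= 2.
#' @return list of class \code{distribution_report} with elements
#'   \code{mean}, \code{sd}, \code{min}, \code{max} (combined sample),
#'   \code{group_means}, \code{levene_stat}, \code{levene_p}, \code{t_stat},
#'   \code{t_df}, \code{t_p}, \code{pooled_variance} (logical) and
#'   \code{qq_points} (data frame theoretical/sample).
#' @export
score_distribution_report <- function(group_a, group_b) {
  if (length(group_a) < 2 || length(group_b) < 2)
    numeric_error("each group needs at least 2 observations")
  x <- c(group_a, group_b)
  g <- factor(rep(c("a", "b"), c(length(group_a), length(group_b))))
  lev <- car::leveneTest(x, g, center = mean)
  levene_stat <- lev[1, "F value"]
  levene_p <- lev[1, "Pr(>F)"]
  if (!is.finite(levene_stat)) { levene_stat <- 0; levene_p <- 1 }
  pooled <- levene_p >= 0.05
  tt <- stats::t.test(group_a, group_b, var.equal = pooled,
                      alternative = "two.sided")
  srt <- sort(x)
  qq <- data.frame(
    theoretical = stats::qnorm(stats::ppoints(length(x)), mean(x),
                               stats::sd(x)),
    sample = srt)
  structure(list(mean = mean(x), sd = stats::sd(x), min = min(x),
                 max = max(x),
                 group_means = c(a = mean(group_a), b = mean(group_b)),
                 levene_stat = unname(levene_stat),
                 levene_p = unname(levene_p),
                 t_stat = unname(tt$statistic), t_df = unname(tt$parameter),
                 t_p = tt$p.value, pooled_variance = pooled,
                 qq_points = qq),
            class = "distribution_report")
}

#' Write scores (and optional categories) as TSV
#' @param scores a \code{score_result}.
#' @param path output path.
#' @param categories optional data frame from \code{\link{categorize_scores}}.
#' @export
write_scores <- function(scores, path, categories = NULL) {
  out <- as.data.frame(scores)
  if (!is.null(categories))
    out$category <- categories$category[match(out$sample_id,
                                              categories$sample_id)]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}
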