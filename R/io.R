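# Readers and writers for the external formats of the pipeline: the SNP
# weights table, genotypes as effect-allele dosage matrix, and the clinical
# phenotype table.  VCF input lives in io_vcf.R.

PHENO_COLS <- c("sample_id", "sex", "is_case", "family_history",
                "early_onset", "bilateral", "ectopic", "recurrence")
PHENO_BINARY <- setdiff(PHENO_COLS, "sample_id")

#' Construct a SNP weight panel
#'
#' A weight panel holds, for each variant, the effect allele whose count is
#' scored and a per-allele weight equal to the natural logarithm of its
#' disease odds ratio.  The panel size \eqn{N} is the number of entries and
#' is the constant used when rescaling scores of partially genotyped
#' samples.
#'
#' @param snp_id character vector of unique variant identifiers.
#' @param chrom chromosome labels (stored verbatim as character).
#' @param pos 1-based positions.
#' @param effect_allele,other_allele allele strings; must differ per SNP.
#' @param or per-effect-allele odds ratios, strictly positive.
#' @return an object of class \code{weight_panel}: a data frame with one row
#'   per SNP and columns \code{snp_id}, \code{chrom}, \code{pos},
#'   \code{effect_allele}, \code{other_allele}, \code{or}, \code{weight}
#'   (\code{log(or)}), with attribute \code{panel_size}.
#' @examples
#' weight_panel("rs1", "7", 1000L, "A", "G", 1.5)
#' @export
weight_panel <- function(snp_id, chrom, pos, effect_allele, other_allele, or) {
  snp_id <- as.character(snp_id)
  if (anyDuplicated(snp_id))
    format_error("duplicate snp_id in weight panel")
  or <- as.numeric(or)
  if (any(!is.finite(or)) || any(or <= 0))
    format_error("odds ratios must be finite and > 0")
  effect_allele <- as.character(effect_allele)
  other_allele <- as.character(other_allele)
  if (any(!nzchar(effect_allele)) || any(!nzchar(other_allele)))
    format_error("alleles must be non-empty strings")
  if (any(effect_allele == other_allele))
    format_error("effect_allele must differ from other_allele")
  pos <- as.integer(pos)
  if (any(is.na(pos)) || any(pos < 1L))
    format_error("pos must be positive integers")
  out <- data.frame(snp_id = snp_id, chrom = as.character(chrom), pos = pos,
                    effect_allele = effect_allele,
                    other_allele = other_allele,
                    or = or, weight = log(or),
                    stringsAsFactors = FALSE)
  structure(out, class = c("weight_panel", "data.frame"),
            panel_size = nrow(out))
}

#' @export
print.weight_panel <- function(x, ...) {
  cat("wGRS weight panel:", attr(x, "panel_size"), "SNPs\n")
  print.data.frame(utils::head(as.data.frame(x), 10), ...)
  if (nrow(x) > 10) cat("...", nrow(x) - 10, "more rows\n")
  invisible(x)
}

#' Panel size of a weight panel
#' @param panel a \code{weight_panel}.
#' @return integer number of SNPs in the panel.
#' @export
panel_size <- function(panel) {
  stopifnot(inherits(panel, "weight_panel"))
  attr(panel, "panel_size")
}

#' Read a SNP weights table
#'
#' The table is tab-separated with header columns exactly \code{snp_id},
#' \code{chrom}, \code{pos}, \code{effect_allele}, \code{other_allele},
#' \code{or}.  Weights are computed as the natural log of the odds ratio;
#' row order is preserved.
#'
#' @param path path to the TSV file.
#' @return a \code{\link{weight_panel}}.
#' @export
read_weight_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("snp_id", "chrom", "pos", "effect_allele", "other_allele", "or")
  miss <- setdiff(need, names(df))
  if (length(miss))
    format_error(paste("weights table missing column(s):",
                       paste(miss, collapse = ", ")))
  or <- suppressWarnings(as.numeric(df$or))
  if (anyNA(or)) format_error("non-numeric odds ratio in weights table")
  weight_panel(df$snp_id, df$chrom, df$pos, df$effect_allele,
               df$other_allele, or)
}

#' Write a weight panel to TSV
#' @param panel a \code{weight_panel}.
#' @param path output path.
#' @export
write_weight_table <- function(panel, path) {
  stopifnot(inherits(panel, "weight_panel"))
  utils::write.table(
    as.data.frame(panel)[c("snp_id", "chrom", "pos", "effect_allele",
                           "other_allele", "or")],
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a genotype matrix of effect-allele counts
#'
#' @param counts numeric matrix, samples in rows and SNPs in columns; every
#'   non-missing entry must be 0, 1 or 2 (the count of the panel's effect
#'   allele); \code{NA} marks a missing genotype.
#' @param sample_ids,snp_ids row and column identities; \code{snp_ids} must
#'   be a subset of the panel's SNPs, in panel order, when a panel is given.
#' @param panel optional \code{weight_panel} to validate against.
#' @return a numeric matrix of class \code{genotype_matrix} with
#'   \code{sample_ids} as rownames and \code{snp_ids} as colnames.
#' @export
genotype_matrix <- function(counts, sample_ids = rownames(counts),
                            snp_ids = colnames(counts), panel = NULL) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  if (is.null(sample_ids) || anyDuplicated(sample_ids))
    format_error("sample ids must be present and unique")
  ok <- counts %in% c(0, 1, 2) | is.na(counts)
  if (!all(ok))
    format_error("genotype counts must be 0, 1, 2 or missing")
  if (!is.null(panel)) {
    keep <- intersect(panel$snp_id, snp_ids)
    if (!identical(as.character(snp_ids), keep))
      format_error("genotype snp_ids must match the panel subset in panel order")
  }
  dimnames(counts) <- list(as.character(sample_ids), as.character(snp_ids))
  structure(counts, class = c("genotype_matrix", class(counts)))
}

#' Read an effect-allele dosage matrix
#'
#' Tab-separated file whose first column is \code{sample_id} and whose
#' remaining columns are SNP identifiers; cells are 0, 1, 2 or \code{NA}.
#' Columns not present in \code{panel} are dropped with a warning; panel
#' SNPs absent from the file become all-missing columns with a warning.
#'
#' @param path path to the TSV file.
#' @param panel a \code{weight_panel} defining SNP order and identity.
#' @return a \code{\link{genotype_matrix}} with columns in panel order.
#' @export
read_dosage_matrix <- function(path, panel) {
  stopifnot(inherits(panel, "weight_panel"))
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                          na.strings = "NA")
  if (names(df)[1] != "sample_id")
    format_error("first column of a dosage matrix must be sample_id")
  ids <- as.character(df$sample_id)
  vals <- as.matrix(df[-1])
  if (!is.numeric(vals)) {
    suppressWarnings(storage.mode(vals) <- "double")
    bad_parse <- is.na(vals) & !is.na(as.matrix(df[-1]))
    if (any(bad_parse)) format_error("non-numeric genotype cell in dosage matrix")
  }
  if (!all(vals %in% c(0, 1, 2) | is.na(vals)))
    format_error("dosage cells must be in {0,1,2,NA}")
  unknown <- setdiff(colnames(vals), panel$snp_id)
  if (length(unknown)) {
    warning("ignoring ", length(unknown), " dosage column(s) not in panel: ",
            paste(unknown, collapse = ", "))
    vals <- vals[, setdiff(colnames(vals), unknown), drop = FALSE]
  }
  absent <- setdiff(panel$snp_id, colnames(vals))
  if (length(absent)) {
    warning(length(absent), " panel SNP(s) absent from dosage file, set missing: ",
            paste(absent, collapse = ", "))
    add <- matrix(NA_real_, nrow(vals), length(absent),
                  dimnames = list(NULL, absent))
    vals <- cbind(vals, add)
  }
  vals <- vals[, panel$snp_id, drop = FALSE]
  genotype_matrix(vals, ids, panel$snp_id, panel)
}

#' Write a genotype matrix as a dosage TSV
#' @param genotypes a \code{genotype_matrix}.
#' @param path output path.
#' @export
write_dosage_matrix <- function(genotypes, path) {
  df <- data.frame(sample_id = rownames(genotypes),
                   as.data.frame(unclass(genotypes)),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Construct a phenotype table
#'
#' Per-sample clinical record with binary fields coded 0/1 (\code{sex}:
#' 0 = female, 1 = male) and \code{NA} for missing.  The diathesis features
#' (\code{family_history}, \code{early_onset}, \code{bilateral},
#' \code{ectopic}) and \code{recurrence} are defined for cases only and must
#' be missing for controls.
#'
#' @param df data frame with columns \code{sample_id}, \code{sex},
#'   \code{is_case}, \code{family_history}, \code{early_onset},
#'   \code{bilateral}, \code{ectopic}, \code{recurrence}.
#' @return a data frame of class \code{phenotype_table}.
#' @export
phenotype_table <- function(df) {
  miss <- setdiff(PHENO_COLS, names(df))
  if (length(miss))
    format_error(paste("phenotype table missing column(s):",
                       paste(miss, collapse = ", ")))
  df <- df[PHENO_COLS]
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id))
    format_error("duplicate sample_id in phenotype table")
  for (col in PHENO_BINARY) {
    v <- df[[col]]
    if (is.character(v)) v <- suppressWarnings(as.numeric(v))
    if (!is_binary01(v))
      format_error(paste0("non-binary code in phenotype field '", col, "'"))
    df[[col]] <- as.numeric(v)
  }
  ctrl <- !is.na(df$is_case) & df$is_case == 0
  case_only <- c("family_history", "early_onset", "bilateral", "ectopic",
                 "recurrence")
  if (any(ctrl) && any(!is.na(as.matrix(df[ctrl, case_only]))))
    format_error("diathesis/recurrence fields must be missing for controls")
  structure(df, class = c("phenotype_table", "data.frame"))
}

#' Read a phenotype CSV
#'
#' Comma-separated file with header columns exactly \code{sample_id},
#' \code{sex}, \code{is_case}, \code{family_history}, \code{early_onset},
#' \code{bilateral}, \code{ectopic}, \code{recurrence}; binary fields coded
#' 0/1/NA.  Missing values are preserved for downstream imputation.
#'
#' @param path path to the CSV file.
#' @return a \code{\link{phenotype_table}}.
#' @export
read_phenotypes <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "NA")
  phenotype_table(df)
}

#' Write a phenotype table as CSV
#' @param phenotypes a \code{phenotype_table}.
#' @param path output path.
#' @export
write_phenotypes <- function(phenotypes, path) {
  utils::write.csv(as.data.frame(phenotypes), path, row.names = FALSE,
                   quote = FALSE, na = "NA")
  invisible(path)
}

#' The synthetic 26-SNP demonstration panel
#'
#' Returns the panel shipped with the package: 26 synthetic biallelic SNPs
#' with odds ratios in the range typical of genome-wide-significant common
#' variants.  The published 26-SNP panel sits behind controlled-access
#' summary data; substitute it by writing a weights TSV with the same
#' columns and calling \code{\link{read_weight_table}}.
#'
#' @return a \code{\link{weight_panel}} of 26 entries.
#' @export
default_panel <- function() {
  read_weight_table(system.file("extdata", "synthetic_panel_26.tsv",
                                package = "wgrs", mustWork = TRUE))
}
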