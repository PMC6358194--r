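# VCF genotype input.  Records are matched to the weight panel by exact id
# and exact allele-set identity; no strand flipping is attempted, because a
# silently flipped allele corrupts every downstream score.

#' Read panel genotypes from a VCF
#'
#' Reads a VCF (v4.2, GT field) and returns effect-allele counts for the
#' SNPs of a weight panel.  A record is used only when its ID equals a
#' panel \code{snp_id} \emph{and} its \{REF, ALT\} allele pair equals the
#' panel's \{effect_allele, other_allele\} pair; an id match with any other
#' allele configuration, or a multiallelic record under a panel id, is a
#' hard error.  Genotypes \code{./.} and \code{.} are missing.  Panel SNPs
#' absent from the file are returned as all-missing columns with a warning.
#'
#' @param path path to a VCF file (plain or gzipped).
#' @param panel a \code{\link{weight_panel}}.
#' @return a \code{\link{genotype_matrix}} with columns in panel order.
#' @export
read_genotypes_vcf <- function(path, panel) {
  stopifnot(inherits(panel, "weight_panel"))
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix)))                      # single-record VCF
    fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  ids <- fix[, "ID"]
  gt <- vcfR::extract.gt(v, element = "GT")
  samples <- colnames(gt)
  n <- length(samples)
  counts <- matrix(NA_real_, n, nrow(panel),
                   dimnames = list(samples, panel$snp_id))
  for (j in seq_len(nrow(panel))) {
    hit <- which(ids == panel$snp_id[j])
    if (!length(hit)) next
    if (length(hit) > 1L)
      format_error(paste0("multiple VCF records for panel SNP ",
                          panel$snp_id[j]))
    ref <- fix[hit, "REF"]; alt <- fix[hit, "ALT"]
    if (grepl(",", alt, fixed = TRUE))
      format_error(paste0("multiallelic VCF record for panel SNP ",
                          panel$snp_id[j]))
    eff <- panel$effect_allele[j]; oth <- panel$other_allele[j]
    if (!setequal(c(ref, alt), c(eff, oth)))
      format_error(paste0("allele mismatch for panel SNP ", panel$snp_id[j],
                          ": VCF ", ref, "/", alt, " vs panel ", eff, "/", oth,
                          " (no strand flipping attempted)"))
    effect_code <- if (alt == eff) "1" else "0"
    calls <- gt[hit, ]
    counts[, j] <- vapply(calls, function(g) {
      if (is.na(g) || g == "." || g == "./." || g == ".|.") return(NA_real_)
      al <- strsplit(g, "[/|]")[[1]]
      if (any(al == ".")) return(NA_real_)
      if (!all(al %in% c("0", "1")))
        format_error(paste0("unexpected allele code in GT '", g, "'"))
      sum(al == effect_code)
    }, numeric(1), USE.NAMES = FALSE)
  }
  absent <- panel$snp_id[colSums(!is.na(counts)) == 0 &
                           !(panel$snp_id %in% ids)]
  if (length(absent))
    warning(length(absent), " panel SNP(s) absent from VCF, set missing: ",
            paste(absent, collapse = ", "))
  genotype_matrix(counts, samples, panel$snp_id, panel)
}
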