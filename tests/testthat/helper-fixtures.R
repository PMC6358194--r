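# Fixture builders shared across test files.  Everything is generated in
# code; no data files.

make_test_panel <- function(ors = c(1.5, 2.0, 1.2),
                            ids = sprintf("rs%03d", seq_along(ors))) {
  n <- length(ors)
  weight_panel(ids, chrom = rep("1", n), pos = seq_len(n) * 100L,
               effect_allele = rep(c("A", "C"), length.out = n),
               other_allele = rep(c("G", "T"), length.out = n),
               or = ors)
}

# random panel + genotypes for oracle sweeps
random_instance <- function(k_max = 30) {
  k <- sample(2:k_max, 1)
  panel <- weight_panel(sprintf("s%d", 1:k), "1", 1:k, "A", "G",
                        or = exp(stats::rnorm(k, 0, 0.5)))
  counts <- matrix(sample(c(0, 1, 2, NA), k * 5, replace = TRUE,
                          prob = c(.3, .3, .3, .1)), 5, k)
  # guarantee each sample has at least one genotyped SNP
  for (i in 1:5) if (all(is.na(counts[i, ]))) counts[i, 1] <- 1
  colnames(counts) <- panel$snp_id
  rownames(counts) <- sprintf("S%d", 1:5)
  list(panel = panel, genotypes = genotype_matrix(counts))
}

# write a minimal VCF for a genotype matrix; effect_is_alt[j] puts the
# panel's effect allele in ALT (TRUE) or REF (FALSE) for SNP j
write_test_vcf <- function(genotypes, panel, path,
                           effect_is_alt = rep(TRUE, nrow(panel))) {
  samples <- rownames(genotypes)
  lines <- c("##fileformat=VCFv4.2",
             "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", samples), collapse = "\t"))
  gt_string <- function(count, is_alt) {
    if (is.na(count)) return("./.")
    alt_copies <- if (is_alt) count else 2 - count
    c("0/0", "0/1", "1/1")[alt_copies + 1]
  }
  for (j in seq_len(nrow(panel))) {
    ref <- if (effect_is_alt[j]) panel$other_allele[j] else panel$effect_allele[j]
    alt <- if (effect_is_alt[j]) panel$effect_allele[j] else panel$other_allele[j]
    gts <- vapply(unclass(genotypes)[, j], gt_string, "",
                  is_alt = effect_is_alt[j])
    lines <- c(lines, paste(c(panel$chrom[j], panel$pos[j], panel$snp_id[j],
                              ref, alt, ".", "PASS", ".", "GT", gts),
                            collapse = "\t"))
  }
  writeLines(lines, path)
  path
}

# small complete case-only analysis table drawn from the generative model
make_case_table <- function(n, beta, seed, delta = rep(0, 4),
                            panel = default_panel(),
                            freqs = default_allele_freqs()) {
  cfg <- simulation_config(n_cases = n, n_controls = 0L, panel = panel,
                           allele_freqs = freqs,
                           genotype_missing_rate = 0,
                           phenotype_missing_rate = 0, seed = seed)
  cfg$recurrence$wgrs_slope <- beta
  cfg$recurrence$feature_effects[] <- delta
  co <- simulate_cohort(cfg)
  sc <- compute_wgrs(co$genotypes, panel)
  analysis_table(co$phenotypes, sc)
}

# MCAR-mask selected columns of a data frame
mask_mcar <- function(df, cols, rate, seed) {
  with_seed <- get("with_seed", asNamespace("wgrs"))
  with_seed(seed, {
    for (col in cols) {
      hit <- stats::runif(nrow(df)) < rate
      df[[col]][hit] <- NA
    }
  })
  df
}
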