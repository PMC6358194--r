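# Synthetic genotype-phenotype cohort generator.  The generative model is a
# chain of logistic regressions: disease status on the raw weighted allele
# burden, each diathesis feature on the wGRS among cases, and surgical
# recurrence on the wGRS plus the diathesis features.  Missingness is
# applied afterwards, missing-completely-at-random, so parameter-recovery
# tests have exact targets.

IMPUTABLE_PHENO <- c("sex", "family_history", "early_onset", "bilateral",
                     "recurrence")
DIATHESIS_FEATURES <- c("family_history", "early_onset", "bilateral",
                        "ectopic")

#' Build a simulation configuration
#'
#' Defines the generative model for one synthetic case-control cohort.
#' Intercepts are on the logit scale; slopes are per-unit log odds ratios.
#' Use \code{\link{calibrate_config}} (or the shipped
#' \code{\link{cohort_config}} presets) to set intercepts so that marginal
#' prevalences hit chosen targets.
#'
#' @param n_cases,n_controls cohort sizes (cases ascertained from a
#'   simulated population; controls are the non-cases).
#' @param panel \code{\link{weight_panel}} whose weights act as the
#'   generative per-allele disease log odds ratios.
#' @param allele_freqs effect-allele frequencies, in (0,1), one per panel
#'   SNP.
#' @param case_intercept logit-scale intercept of the disease model
#'   \code{P(case) = logistic(case_intercept + raw weighted sum)}.
#' @param male_prob probability a sample is male (sex is independent of
#'   genotype in the generator).
#' @param diathesis named list over \code{family_history}, \code{early_onset},
#'   \code{bilateral}, \code{ectopic}; each element
#'   \code{list(intercept=, slope=)} with slope the per-unit wGRS log-OR for
#'   expressing the feature (cases only).
#' @param recurrence \code{list(intercept=, wgrs_slope=, feature_effects=)}
#'   where \code{feature_effects} is a named numeric vector of per-feature
#'   log-ORs on recurrence.
#' @param genotype_missing_rate,phenotype_missing_rate MCAR rates in [0,1].
#' @param seed master seed; named substreams (genotypes, phenotypes,
#'   missingness) are derived from it so adding a stage never perturbs
#'   earlier draws.
#' @param label cohort label used as the sample-id prefix.
#' @return list of class \code{simulation_config}.
#' @export
simulation_config <- function(n_cases, n_controls = 0L,
                              panel = default_panel(),
                              allele_freqs = default_allele_freqs(),
                              case_intercept = -6.4,
                              male_prob = 0.75,
                              diathesis = list(
                                family_history = list(intercept = -1.5, slope = log(1.2)),
                                early_onset    = list(intercept = -1.8, slope = log(1.2)),
                                bilateral      = list(intercept = -0.6, slope = log(1.2)),
                                ectopic        = list(intercept = -3.3, slope = log(1.2))),
                              recurrence = list(
                                intercept = -2.5,
                                wgrs_slope = log(1.18),
                                feature_effects = c(family_history = log(1.5),
                                                    early_onset = log(2.2),
                                                    bilateral = log(1.6),
                                                    ectopic = log(1.4))),
                              genotype_missing_rate = 0.02,
                              phenotype_missing_rate = 0.05,
                              seed = 1L, label = "SIM") {
  cfg <- list(n_cases = as.integer(n_cases), n_controls = as.integer(n_controls),
              panel = panel, allele_freqs = as.numeric(allele_freqs),
              case_intercept = case_intercept, male_prob = male_prob,
              diathesis = diathesis, recurrence = recurrence,
              genotype_missing_rate = genotype_missing_rate,
              phenotype_missing_rate = phenotype_missing_rate,
              seed = as.integer(seed), label = label)
  validate_config(cfg)
  structure(cfg, class = "simulation_config")
}

validate_config <- function(cfg) {
  if (cfg$n_cases < 1L || cfg$n_controls < 0L)
    config_error("n_cases must be >= 1 and n_controls >= 0")
  if (!inherits(cfg$panel, "weight_panel"))
    config_error("panel must be a weight_panel")
  if (length(cfg$allele_freqs) != panel_size(cfg$panel))
    config_error("allele_freqs length must equal the panel size")
  if (any(cfg$allele_freqs <= 0 | cfg$allele_freqs >= 1))
    config_error("allele frequencies must lie strictly in (0,1)")
  rates <- c(cfg$genotype_missing_rate, cfg$phenotype_missing_rate)
  if (any(rates < 0 | rates > 1))
    config_error("missingness rates must lie in [0,1]")
  if (!setequal(names(cfg$diathesis), DIATHESIS_FEATURES))
    config_error("diathesis must name family_history, early_onset, bilateral, ectopic")
  fe <- cfg$recurrence$feature_effects
  if (!setequal(names(fe), DIATHESIS_FEATURES))
    config_error("recurrence feature_effects must cover the four diathesis features")
  invisible(TRUE)
}

#' Default effect-allele frequencies for the shipped panel
#'
#' Common-variant frequencies descending from 0.60 to 0.20, paired with the
#' shipped panel's descending odds ratios; chosen so the complete-data score
#' distribution has mean near 6.3 and SD near 1.
#' @return numeric vector of length 26.
#' @export
default_allele_freqs <- function() {
  rev(round(seq(0.20, 0.60, length.out = 26), 3))
}

#' Simulate Hardy-Weinberg genotypes
#'
#' Effect-allele counts drawn independently per SNP as Binomial(2, p), i.e.
#' Hardy-Weinberg proportions with no linkage disequilibrium.
#'
#' @param n number of samples.
#' @param freqs effect-allele frequencies in (0,1).
#' @param seed integer seed.
#' @param snp_ids,sample_prefix column names and sample-id prefix.
#' @return a \code{\link{genotype_matrix}} with no missing entries.
#' @export
simulate_genotypes <- function(n, freqs, seed,
                               snp_ids = sprintf("snp%02d", seq_along(freqs)),
                               sample_prefix = "S") {
  if (any(freqs <= 0 | freqs >= 1))
    config_error("allele frequencies must lie strictly in (0,1)")
  counts <- with_seed(seed, {
    m <- vapply(freqs, function(p) stats::rbinom(n, 2L, p), numeric(n))
    if (n == 1L) m <- matrix(m, nrow = 1L)
    m
  })
  ids <- sprintf("%s%06d", sample_prefix, seq_len(n))
  genotype_matrix(counts, ids, snp_ids)
}

# logistic draw helper
rbern_logit <- function(lp) stats::rbinom(length(lp), 1L, stats::plogis(lp))

#' Simulate phenotypes for given complete genotypes
#'
#' Computes each sample's true wGRS from the complete genotypes, draws case
#' status from the disease model, and — for cases only — draws the four
#' diathesis features and recurrence from their logistic models.  Controls
#' carry missing diathesis and recurrence values, mirroring a case-only
#' outcome design.
#'
#' @param genotypes complete \code{\link{genotype_matrix}} matching the
#'   config's panel.
#' @param config a \code{\link{simulation_config}}.
#' @param seed seed for the phenotype draws (default: the config's
#'   phenotype substream).
#' @return a list of class \code{simulated_cohort}: \code{genotypes},
#'   \code{phenotypes} (a \code{\link{phenotype_table}}), and \code{truth}
#'   (config, per-sample true wGRS, complete copies of both tables).
#' @export
simulate_phenotypes <- function(genotypes, config,
                                seed = derive_seeds(config$seed, "phenotypes")) {
  validate_config(config)
  if (!identical(colnames(genotypes), config$panel$snp_id))
    config_error("genotype snp_ids incompatible with the config's panel")
  if (anyNA(unclass(genotypes)))
    config_error("simulate_phenotypes requires complete genotypes; apply missingness afterwards")
  sc <- compute_wgrs(genotypes, config$panel)
  # complete data: scaled score equals the raw weighted sum
  wgrs <- sc$scaled_score
  n <- nrow(genotypes)
  ph <- with_seed(seed, {
    sex <- stats::rbinom(n, 1L, config$male_prob)
    is_case <- rbern_logit(config$case_intercept + sc$raw_sum)
    feats <- matrix(NA_real_, n, 4,
                    dimnames = list(NULL, DIATHESIS_FEATURES))
    rec <- rep(NA_real_, n)
    idx <- which(is_case == 1L)
    if (length(idx)) {
      for (f in DIATHESIS_FEATURES) {
        par <- config$diathesis[[f]]
        feats[idx, f] <- rbern_logit(par$intercept + par$slope * wgrs[idx])
      }
      lp <- config$recurrence$intercept +
        config$recurrence$wgrs_slope * wgrs[idx] +
        drop(feats[idx, DIATHESIS_FEATURES, drop = FALSE] %*%
               config$recurrence$feature_effects[DIATHESIS_FEATURES])
      rec[idx] <- rbern_logit(lp)
    }
    data.frame(sample_id = rownames(genotypes), sex = as.numeric(sex),
               is_case = as.numeric(is_case),
               family_history = feats[, "family_history"],
               early_onset = feats[, "early_onset"],
               bilateral = feats[, "bilateral"],
               ectopic = feats[, "ectopic"],
               recurrence = rec, stringsAsFactors = FALSE)
  })
  phenotypes <- phenotype_table(ph)
  structure(list(genotypes = genotypes, phenotypes = phenotypes,
                 truth = list(config = config,
                              true_wgrs = stats::setNames(wgrs, sc$sample_id),
                              complete_genotypes = genotypes,
                              complete_phenotypes = phenotypes)),
            class = "simulated_cohort")
}

#' Apply missing-completely-at-random masking to a cohort
#'
#' Each genotype cell is set missing with \code{genotype_rate}; each
#' imputable phenotype cell (\code{sex} for everyone; \code{family_history},
#' \code{early_onset}, \code{bilateral}, \code{recurrence} for cases) is set
#' missing with \code{phenotype_rate}.  Ectopic disease is never masked by
#' default, mirroring a variable observed without missingness.  The
#' pre-masking truth is retained in \code{cohort$truth}.
#'
#' @param cohort a \code{simulated_cohort}.
#' @param genotype_rate,phenotype_rate MCAR rates in [0,1].
#' @param seed integer seed.
#' @param mask_ectopic set \code{TRUE} to mask ectopic disease as well.
#' @return the cohort with masked \code{genotypes} and \code{phenotypes}.
#' @export
apply_missingness <- function(cohort, genotype_rate, phenotype_rate, seed,
                              mask_ectopic = FALSE) {
  stopifnot(inherits(cohort, "simulated_cohort"))
  if (genotype_rate < 0 || genotype_rate > 1 ||
      phenotype_rate < 0 || phenotype_rate > 1)
    config_error("missingness rates must lie in [0,1]")
  g <- unclass(cohort$genotypes)
  ph <- as.data.frame(cohort$phenotypes)
  with_seed(seed, {
    if (genotype_rate > 0) {
      mask <- matrix(stats::runif(length(g)) < genotype_rate, nrow(g))
      g[mask] <- NA_real_
    }
    cols <- IMPUTABLE_PHENO
    if (mask_ectopic) cols <- c(cols, "ectopic")
    if (phenotype_rate > 0) {
      for (col in cols) {
        eligible <- if (col == "sex") rep(TRUE, nrow(ph))
                    else !is.na(ph$is_case) & ph$is_case == 1
        hit <- eligible & stats::runif(nrow(ph)) < phenotype_rate
        ph[[col]][hit] <- NA_real_
      }
    }
  })
  cohort$genotypes <- genotype_matrix(g, rownames(g), colnames(g))
  cohort$phenotypes <- phenotype_table(ph)
  cohort
}

#' Simulate one ascertained case-control cohort
#'
#' Repeatedly simulates population batches (genotypes then phenotypes) and
#' retains samples until the configured case and control quotas are met,
#' then applies MCAR missingness at the configured rates.  Fully
#' deterministic under the config's seed.
#'
#' @param config a \code{\link{simulation_config}}.
#' @return a \code{simulated_cohort}; samples are relabelled
#'   \code{<label><000001...>}, cases first.
#' @export
simulate_cohort <- function(config) {
  validate_config(config)
  streams <- derive_seeds(config$seed,
                          c("genotypes", "phenotypes", "missingness"))
  need_cases <- config$n_cases
  need_ctrls <- config$n_controls
  got_g <- list(); got_p <- list()
  batch <- 0L
  max_batches <- 10000L
  while (need_cases > 0L || need_ctrls > 0L) {
    batch <- batch + 1L
    if (batch > max_batches)
      config_error("ascertainment failed: case/control quotas unreachable under this config")
    bn <- max(1000L, 2L * (need_cases + need_ctrls))
    g <- simulate_genotypes(bn, config$allele_freqs,
                            seed = (streams[["genotypes"]] + batch) %% .Machine$integer.max,
                            snp_ids = config$panel$snp_id,
                            sample_prefix = sprintf("B%04d_", batch))
    sim <- simulate_phenotypes(g, config,
                               seed = (streams[["phenotypes"]] + batch) %% .Machine$integer.max)
    pc <- as.data.frame(sim$phenotypes)
    take_case <- utils::head(which(pc$is_case == 1), need_cases)
    take_ctrl <- utils::head(which(pc$is_case == 0), need_ctrls)
    take <- c(take_case, take_ctrl)
    if (length(take)) {
      got_g[[batch]] <- unclass(sim$genotypes)[take, , drop = FALSE]
      got_p[[batch]] <- pc[take, , drop = FALSE]
      need_cases <- need_cases - length(take_case)
      need_ctrls <- need_ctrls - length(take_ctrl)
    }
  }
  g <- do.call(rbind, got_g)
  ph <- do.call(rbind, got_p)
  ord <- order(-ph$is_case)
  g <- g[ord, , drop = FALSE]
  ph <- ph[ord, , drop = FALSE]
  ids <- sprintf("%s%06d", config$label, seq_len(nrow(ph)))
  rownames(g) <- ids
  ph$sample_id <- ids
  rownames(ph) <- NULL
  genotypes <- genotype_matrix(g, ids, config$panel$snp_id, config$panel)
  phenotypes <- phenotype_table(ph)
  sc <- compute_wgrs(genotypes, config$panel)
  cohort <- structure(list(genotypes = genotypes, phenotypes = phenotypes,
                           truth = list(config = config,
                                        true_wgrs = stats::setNames(sc$scaled_score,
                                                                    sc$sample_id),
                                        complete_genotypes = genotypes,
                                        complete_phenotypes = phenotypes)),
                      class = "simulated_cohort")
  apply_missingness(cohort, config$genotype_missing_rate,
                    config$phenotype_missing_rate,
                    seed = streams[["missingness"]])
}

#' Simulate two independently ascertained cohorts
#'
#' @param config_a,config_b \code{\link{simulation_config}}s (defaults: the
#'   shipped presets of 6126 and 1730 cases).  When both configs carry the
#'   same seed, the second cohort's seed is re-derived so the cohorts are
#'   independent.
#' @return named list of two \code{simulated_cohort}s.
#' @export
simulate_two_cohorts <- function(config_a = cohort_config("uk"),
                                 config_b = cohort_config("nl")) {
  if (identical(config_a$seed, config_b$seed))
    config_b$seed <- unname(derive_seeds(config_b$seed, "second_cohort"))
  list(a = simulate_cohort(config_a), b = simulate_cohort(config_b))
}

#' Calibrate config intercepts to target prevalences by root-finding
#'
#' Simulates a calibration population from the config's panel and allele
#' frequencies (fixed internal seed, independent of the config's seed),
#' then solves, by \code{\link[stats]{uniroot}} on the intercept, for the
#' marginal prevalence of (i) case status in the population, (ii) each
#' diathesis feature among cases, and (iii) recurrence among cases.
#'
#' @param config a \code{\link{simulation_config}}.
#' @param targets named list: \code{case} (population case fraction),
#'   \code{diathesis} (named vector of case prevalences for the four
#'   features) and \code{recurrence} (case prevalence).
#' @param n_calib calibration sample size (default 50000).
#' @return the config with calibrated intercepts.
#' @export
calibrate_config <- function(config, targets, n_calib = 50000L) {
  validate_config(config)
  g <- simulate_genotypes(n_calib, config$allele_freqs, seed = 761543L,
                          snp_ids = config$panel$snp_id)
  sc <- compute_wgrs(g, config$panel)
  solve_icpt <- function(lp, target) {
    stats::uniroot(function(a) mean(stats::plogis(a + lp)) - target,
                   interval = c(-40, 40), tol = 1e-10)$root
  }
  config$case_intercept <- solve_icpt(sc$raw_sum, targets$case)
  # condition on case status for the case-only models
  keep <- with_seed(761544L,
                    which(rbern_logit(config$case_intercept + sc$raw_sum) == 1L))
  wg <- sc$scaled_score[keep]
  feats <- matrix(0, length(wg), 4, dimnames = list(NULL, DIATHESIS_FEATURES))
  for (f in DIATHESIS_FEATURES) {
    sl <- config$diathesis[[f]]$slope
    config$diathesis[[f]]$intercept <-
      solve_icpt(sl * wg, targets$diathesis[[f]])
    feats[, f] <- with_seed(761545L,
                            rbern_logit(config$diathesis[[f]]$intercept + sl * wg))
  }
  lp <- config$recurrence$wgrs_slope * wg +
    drop(feats %*% config$recurrence$feature_effects[DIATHESIS_FEATURES])
  config$recurrence$intercept <- solve_icpt(lp, targets$recurrence)
  config
}

#' Shipped two-cohort presets
#'
#' Preset configurations for the two synthetic cohorts the package's demo
#' pipeline analyzes: a large cohort of 6126 cases and a smaller replication
#' cohort of 1730 cases, with roughly 3:1 male:female ratio, bilateral
#' disease prevalences of 63\% and 40\%, ectopic disease near 10\%, and
#' per-unit wGRS-recurrence odds ratios of 1.18 and 1.22.  Intercepts are
#' calibrated by \code{\link{calibrate_config}} at build time of the config.
#'
#' @param cohort \code{"uk"} (6126 cases) or \code{"nl"} (1730 cases).
#' @param seed master seed for the cohort.
#' @param n_cases,n_controls override the preset sizes (useful for
#'   scaled-down runs).
#' @return a calibrated \code{\link{simulation_config}}.
#' @export
cohort_config <- function(cohort = c("uk", "nl"), seed = 1L,
                          n_cases = NULL, n_controls = NULL) {
  cohort <- match.arg(cohort)
  preset <- switch(cohort,
    uk = list(n_cases = 6126L, n_controls = 6000L, label = "UK",
              beta = log(1.18),
              targets = list(case = 0.5,
                             diathesis = c(family_history = 0.44,
                                           early_onset = 0.38,
                                           bilateral = 0.63,
                                           ectopic = 0.10),
                             recurrence = 0.30)),
    nl = list(n_cases = 1730L, n_controls = 1700L, label = "NL",
              beta = log(1.22),
              targets = list(case = 0.5,
                             diathesis = c(family_history = 0.38,
                                           early_onset = 0.34,
                                           bilateral = 0.40,
                                           ectopic = 0.12),
                             recurrence = 0.25)))
  cfg <- simulation_config(
    n_cases = if (is.null(n_cases)) preset$n_cases else n_cases,
    n_controls = if (is.null(n_controls)) preset$n_controls else n_controls,
    seed = seed, label = preset$label)
  cfg$recurrence$wgrs_slope <- preset$beta
  calibrate_config(cfg, preset$targets)
}
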