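# End-to-end orchestration: simulate (or read) -> filter and score ->
# impute -> associate -> meta-analyze, with every artifact written to disk
# alongside a provenance sidecar, and a run manifest tying the stages
# together.  Deterministic for a fixed config and seed.

#' Build a pipeline configuration
#'
#' Exactly one of \code{inputs} (paths to weights/genotypes/phenotypes
#' files) or \code{simulate} (named list of \code{simulation_config}s, one
#' per cohort) must be supplied.
#'
#' @param out_dir output directory (created if needed).
#' @param seed master seed recorded in every sidecar; cohort simulation
#'   seeds are derived from it when simulating.
#' @param simulate named list of \code{\link{simulation_config}} objects.
#' @param inputs list with \code{weights}, \code{genotypes},
#'   \code{genotype_format} ("dosage" or "vcf") and \code{phenotypes}.
#' @param min_genotyped exclusion threshold for
#'   \code{\link{filter_low_genotyping}}.
#' @param mice list with \code{m} and \code{cycles} (defaults 75 and 100).
#' @param analyses character vector of analyses to run, any of
#'   \code{"distribution"}, \code{"per_unit"}, \code{"category"},
#'   \code{"diathesis_count"}, \code{"category_diathesis"}, \code{"meta"}.
#' @return list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(out_dir, seed = 1L, simulate = NULL,
                            inputs = NULL, min_genotyped = 2L,
                            mice = list(m = 75L, cycles = 100L),
                            analyses = c("distribution", "per_unit",
                                         "category", "diathesis_count",
                                         "meta")) {
  if (is.null(simulate) == is.null(inputs))
    config_error("provide exactly one of 'simulate' or 'inputs'")
  if (!is.null(simulate)) {
    if (is.null(names(simulate)) || any(!nzchar(names(simulate))))
      config_error("simulate must be a named list of simulation configs")
    for (cfg in simulate)
      if (!inherits(cfg, "simulation_config"))
        config_error("simulate entries must be simulation_config objects")
  }
  if (!is.null(inputs)) {
    need <- c("weights", "genotypes", "genotype_format", "phenotypes")
    if (!all(need %in% names(inputs)))
      config_error(paste("inputs needs:", paste(need, collapse = ", ")))
    if (!inputs$genotype_format %in% c("dosage", "vcf"))
      config_error("genotype_format must be 'dosage' or 'vcf'")
  }
  known <- c("distribution", "per_unit", "category", "diathesis_count",
             "category_diathesis", "meta")
  bad <- setdiff(analyses, known)
  if (length(bad))
    config_error(paste("unknown analyses:", paste(bad, collapse = ", ")))
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 simulate = simulate, inputs = inputs,
                 min_genotyped = as.integer(min_genotyped),
                 mice = mice, analyses = analyses),
            class = "pipeline_config")
}

#' Scaled-down two-cohort demonstration configuration
#'
#' The shipped demo: two simulated cohorts with the presets' prevalence
#' structure at reduced size, and a reduced imputation effort, so the full
#' pipeline runs in about a minute.
#'
#' @param out_dir output directory.
#' @param seed master seed.
#' @param n_cases_a,n_cases_b,n_controls_a,n_controls_b cohort sizes.
#' @param m,cycles imputation effort.
#' @return a \code{\link{pipeline_config}}.
#' @export
demo_pipeline_config <- function(out_dir, seed = 1L,
                                 n_cases_a = 500L, n_controls_a = 500L,
                                 n_cases_b = 300L, n_controls_b = 300L,
                                 m = 3L, cycles = 5L) {
  seeds <- derive_seeds(seed, c("uk", "nl"))
  pipeline_config(
    out_dir = out_dir, seed = seed,
    simulate = list(
      uk = cohort_config("uk", seed = seeds[["uk"]], n_cases = n_cases_a,
                         n_controls = n_controls_a),
      nl = cohort_config("nl", seed = seeds[["nl"]], n_cases = n_cases_b,
                         n_controls = n_controls_b)),
    mice = list(m = m, cycles = cycles))
}

write_sidecar <- function(path, stage, seed, inputs) {
  yaml::write_yaml(list(stage = stage, seed = as.integer(seed),
                        inputs = inputs),
                   paste0(path, ".provenance.yaml"))
}

fit_rows <- function(fit) {
  if (is.null(fit)) return(NULL)
  if (inherits(fit, "wgrs_fit")) cbind(fit$terms, n = fit$n) else
    as.data.frame(fit)
}

#' Run the full pipeline
#'
#' Stages, in order, per cohort: (1) load or simulate genotypes and
#' phenotypes; (2) exclude samples genotyped at fewer than
#' \code{min_genotyped} SNPs (count logged and recorded in the manifest);
#' (3) compute and categorize scores; (4) distributional report (cases vs
#' controls when controls exist, else women vs men); (5) chained-equations
#' imputation of the case-only analysis table; (6) pooled per-unit,
#' category, and diathesis-count recurrence models.  Finally the per-unit
#' estimates are combined across cohorts by fixed-effect inverse-variance
#' meta-analysis.  Every output TSV gets a provenance sidecar; the manifest
#' (JSON) records inputs, seeds, counts and artifact paths.
#'
#' @param config a \code{\link{pipeline_config}}.
#' @return the manifest, invisibly (also written to
#'   \code{out_dir/manifest.json}).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out, "data"), showWarnings = FALSE)
  manifest <- list(seed = config$seed,
                   package_version = as.character(utils::packageVersion("wgrs")),
                   analyses = config$analyses, cohorts = list(),
                   artifacts = character())
  add_artifact <- function(p) manifest$artifacts <<- c(manifest$artifacts,
                                                       basename(p))
  cohorts <- list()
  if (!is.null(config$simulate)) {
    for (nm in names(config$simulate)) {
      cfg <- config$simulate[[nm]]
      cohort <- simulate_cohort(cfg)
      gpath <- file.path(out, "data", paste0(nm, "_genotypes.tsv"))
      ppath <- file.path(out, "data", paste0(nm, "_phenotypes.csv"))
      wpath <- file.path(out, "data", paste0(nm, "_weights.tsv"))
      write_dosage_matrix(cohort$genotypes, gpath)
      write_phenotypes(cohort$phenotypes, ppath)
      write_weight_table(cfg$panel, wpath)
      for (p in c(gpath, ppath, wpath)) {
        write_sidecar(p, "simulate", cfg$seed,
                      list(label = cfg$label, n_cases = cfg$n_cases,
                           n_controls = cfg$n_controls))
        add_artifact(p)
      }
      cohorts[[nm]] <- list(panel = cfg$panel, genotypes = cohort$genotypes,
                            phenotypes = cohort$phenotypes)
    }
  } else {
    panel <- read_weight_table(config$inputs$weights)
    genotypes <- if (config$inputs$genotype_format == "vcf")
      read_genotypes_vcf(config$inputs$genotypes, panel)
    else read_dosage_matrix(config$inputs$genotypes, panel)
    cohorts[["cohort1"]] <- list(panel = panel, genotypes = genotypes,
                                 phenotypes = read_phenotypes(config$inputs$phenotypes))
  }
  per_unit_pooled <- list(unadjusted = list(), adjusted = list())
  for (nm in names(cohorts)) {
    co <- cohorts[[nm]]
    info <- list(n_samples = nrow(co$genotypes))
    flt <- filter_low_genotyping(co$genotypes, config$min_genotyped)
    info$n_excluded_low_genotyping <- length(flt$excluded)
    scores <- compute_wgrs(flt$retained, co$panel)
    ph <- co$phenotypes[co$phenotypes$sample_id %in% scores$sample_id |
                          !co$phenotypes$sample_id %in% rownames(co$genotypes), ]
    cases <- analysis_table(ph, scores, cases_only = TRUE)
    cats <- categorize_scores(
      scores[scores$sample_id %in% cases$sample_id, ])
    spath <- file.path(out, paste0(nm, "_scores.tsv"))
    write_scores(scores, spath, cats)
    write_sidecar(spath, "score", config$seed,
                  list(min_genotyped = config$min_genotyped))
    add_artifact(spath)
    info$n_cases <- nrow(cases)
    if ("distribution" %in% config$analyses) {
      ctrl_ids <- ph$sample_id[!is.na(ph$is_case) & ph$is_case == 0]
      sc_case <- scores$scaled_score[scores$sample_id %in% cases$sample_id]
      sc_ctrl <- scores$scaled_score[scores$sample_id %in% ctrl_ids]
      rep_groups <- if (length(sc_ctrl) >= 2) list(a = sc_case, b = sc_ctrl)
        else {
          sex <- cases$sex[match(scores$sample_id, cases$sample_id)]
          list(a = scores$scaled_score[!is.na(sex) & sex == 0],
               b = scores$scaled_score[!is.na(sex) & sex == 1])
        }
      dr <- score_distribution_report(rep_groups$a, rep_groups$b)
      dpath <- file.path(out, paste0(nm, "_distribution.tsv"))
      utils::write.table(
        data.frame(stat = c("mean", "sd", "min", "max", "mean_group_a",
                            "mean_group_b", "levene_stat", "levene_p",
                            "t_stat", "t_p"),
                   value = c(dr$mean, dr$sd, dr$min, dr$max,
                             dr$group_means["a"], dr$group_means["b"],
                             dr$levene_stat, dr$levene_p, dr$t_stat, dr$t_p)),
        dpath, sep = "\t", quote = FALSE, row.names = FALSE)
      qpath <- file.path(out, paste0(nm, "_qq.tsv"))
      utils::write.table(dr$qq_points, qpath, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      for (p in c(dpath, qpath)) {
        write_sidecar(p, "distribution", config$seed, list(cohort = nm))
        add_artifact(p)
      }
    }
    # imputation of the case-only analysis table
    mdat <- cases
    names(mdat)[names(mdat) == "wgrs"] <- "wgrs"
    impute_ectopic <- anyNA(mdat$ectopic)
    plan <- default_mice_plan(impute_ectopic = impute_ectopic,
                              m = config$mice$m, cycles = config$mice$cycles,
                              seed = unname(derive_seeds(config$seed,
                                                         paste0("mice_", nm))))
    stack <- mice_impute(mdat, plan)
    info$mice <- list(m = plan$m, cycles = plan$cycles,
                      impute_ectopic = impute_ectopic)
    if ("per_unit" %in% config$analyses) {
      for (kind in c("unadjusted", "adjusted")) {
        adj <- if (kind == "adjusted") DIATHESIS_FEATURES else character()
        pooled <- per_unit_association(stack, adjust = adj)
        per_unit_pooled[[kind]][[nm]] <-
          pooled[pooled$term == "wgrs", , drop = FALSE]
        fpath <- file.path(out, paste0(nm, "_per_unit_", kind, ".tsv"))
        utils::write.table(fit_rows(pooled), fpath, sep = "\t",
                           quote = FALSE, row.names = FALSE)
        write_sidecar(fpath, "association_per_unit", config$seed,
                      list(cohort = nm, adjusted = kind == "adjusted"))
        add_artifact(fpath)
      }
    }
    if ("category" %in% config$analyses) {
      rc <- recurrence_by_category(stack)
      for (kind in c("unadjusted", "adjusted")) {
        fpath <- file.path(out, paste0(nm, "_category_", kind, ".tsv"))
        utils::write.table(fit_rows(rc[[kind]]), fpath, sep = "\t",
                           quote = FALSE, row.names = FALSE)
        write_sidecar(fpath, "association_category", config$seed,
                      list(cohort = nm, adjusted = kind == "adjusted"))
        add_artifact(fpath)
      }
    }
    if ("diathesis_count" %in% config$analyses) {
      dc <- diathesis_count_analysis(stack)
      fpath <- file.path(out, paste0(nm, "_diathesis_count.tsv"))
      utils::write.table(fit_rows(dc$fit), fpath, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      write_sidecar(fpath, "association_diathesis_count", config$seed,
                    list(cohort = nm,
                         unavailable_levels = dc$unavailable))
      add_artifact(fpath)
    }
    if ("category_diathesis" %in% config$analyses) {
      for (f in DIATHESIS_FEATURES) {
        cd <- category_diathesis_association(stack, f)
        tab <- do.call(rbind, lapply(names(cd), function(k)
          cbind(category = k, as.data.frame(cd[[k]]))))
        fpath <- file.path(out, paste0(nm, "_category_", f, ".tsv"))
        utils::write.table(tab, fpath, sep = "\t", quote = FALSE,
                           row.names = FALSE)
        write_sidecar(fpath, "association_category_diathesis", config$seed,
                      list(cohort = nm, feature = f))
        add_artifact(fpath)
      }
    }
    manifest$cohorts[[nm]] <- info
  }
  if ("meta" %in% config$analyses && "per_unit" %in% config$analyses &&
      length(cohorts) >= 2) {
    for (kind in c("unadjusted", "adjusted")) {
      ests <- per_unit_pooled[[kind]]
      studies <- do.call(rbind, lapply(names(ests), function(nm)
        study_estimate(nm, ests[[nm]]$q_bar, ests[[nm]]$se)))
      meta <- fixed_effect_meta(studies)
      mpath <- file.path(out, paste0("meta_per_unit_", kind, ".tsv"))
      write_meta(meta, mpath)
      write_sidecar(mpath, "meta", config$seed,
                    list(studies = names(ests), adjusted = kind == "adjusted"))
      add_artifact(mpath)
    }
  }
  manifest$artifacts <- sort(unique(manifest$artifacts))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
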