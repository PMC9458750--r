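#' Run the full biomarker-correlates pipeline
#'
#' Orchestrates simulate (or load) -> flow phenotyping -> expansion kinetics
#' -> censored cytokine LMEs -> expression normalization and gene-set tests
#' -> efficacy/correlate statistics, writing one report directory of CSV/JSON
#' tables mirroring the study's figure-level summaries plus a run manifest
#' with input/output digests. Stage-level record counts (QC removals,
#' floored gates, dropped gene sets) are logged in the manifest so filtering
#' bookkeeping is auditable. Reruns with the same config and seed reproduce
#' identical digests.
#'
#' @param config a [sim_config()]; its `seed` drives every stochastic stage.
#' @param out_dir report directory (created).
#' @param trial optionally, an existing `trial_dataset` to analyse instead of
#'   simulating.
#' @param perm_B permutations for the gene-set tests (study profile 5000;
#'   reduced profiles for quick runs).
#' @param boot_B bootstrap resamples for median regression (study profile
#'   10000).
#' @return the manifest list, invisibly; files under `out_dir`.
#' @export
run_pipeline <- function(config = sim_config(), out_dir, trial = NULL,
                         perm_B = 5000, boot_B = 10000) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  warnings_log <- character()
  note <- function(fmt, ...) {
    warnings_log <<- c(warnings_log, sprintf(fmt, ...))
  }

  if (is.null(trial)) trial <- simulate_trial(config)
  input_dir <- file.path(out_dir, "inputs")
  write_trial(trial, input_dir)
  patients <- trial$patients

  # efficacy
  eff <- efficacy_table(patients)
  write_csv_exact(eff, file.path(out_dir, "efficacy_table.csv"))

  # IL-15 pre-infusion (day 0) association with response
  il15 <- trial$cytokines[trial$cytokines$analyte == "IL-15" &
                            trial$cytokines$timepoint == "d0", ]
  il15$responder <- patients$responder[match(il15$patient_id, patients$patient_id)]
  il15$cohort <- patients$cohort[match(il15$patient_id, patients$patient_id)]
  wt <- wilcoxon_rank_sum(log(il15$value[il15$responder]),
                          log(il15$value[!il15$responder]))
  tt <- stats::t.test(log(value) ~ responder, data = il15)
  bmr <- bootstrap_median_regression(
    log(il15$value), il15$responder,
    covariates = data.frame(cohort = factor(il15$cohort)),
    B = boot_B, seed = derive_seed(config$seed, "bootstrap"))
  il15_tab <- data.frame(
    median_responder = stats::median(il15$value[il15$responder]),
    median_nonresponder = stats::median(il15$value[!il15$responder]),
    wilcoxon_p = wt$p, t_test_p = tt$p.value,
    median_reg_coef = bmr$coef, median_reg_boot_p = bmr$p
  )
  write_csv_exact(il15_tab, file.path(out_dir, "il15_preinfusion.csv"))

  # expansion kinetics and correlates
  es <- expansion_summary(trial$expansion)
  es <- merge(es, patients[, c("patient_id", "responder", "ldr", "weight_kg",
                               "transduced_cell_dose", "pfs_days", "pfs_event")],
              by = "patient_id")
  es$log_cmax <- ifelse(es$cmax > 0, log(es$cmax), NA)
  es$log_dose_kg <- log(es$transduced_cell_dose / es$weight_kg)
  lmfit <- stats::lm(log_cmax ~ log_dose_kg + ldr, data = es)
  cox <- km_logrank_cox(es$pfs_days, es$pfs_event, covariate = es$log_cmax)$cox
  assoc <- data.frame(
    cmax_responder_wilcoxon_p =
      wilcoxon_rank_sum(es$log_cmax[es$responder], es$log_cmax[!es$responder])$p,
    dose_kg_coef = stats::coef(lmfit)[["log_dose_kg"]],
    ldr_standard_coef = stats::coef(lmfit)[["ldrstandard_fluCy"]],
    spearman_cmax_auc = spearman_test(es$cmax, es$auc_0_28)$rho,
    cox_pfs_log_cmax = cox$log_hr, cox_pfs_p = cox$p
  )
  write_csv_exact(es[, c("patient_id", "cmax", "tmax_day", "auc_0_28",
                         "persistence_wk4")],
                  file.path(out_dir, "expansion_summary.csv"))
  write_csv_exact(assoc, file.path(out_dir, "expansion_correlates.csv"))

  # flow phenotyping
  doses <- phenotype_dose_table(trial$flow_counts, trial$noise, patients)
  note("flow QC removed %d sample(s)", nrow(attr(doses, "qc_rejected")))
  write_csv_exact(doses, file.path(out_dir, "phenotype_doses.csv"))
  em <- doses[doses$parent == "CD8Pent" & doses$phenotype == "EM", ]
  em$responder <- patients$responder[match(em$patient_id, patients$patient_id)]
  em_test <- wilcoxon_rank_sum(em$n_cells_per_kg[em$responder],
                               em$n_cells_per_kg[!em$responder])
  write_csv_exact(data.frame(
    median_em_kg_responder = stats::median(em$n_cells_per_kg[em$responder], na.rm = TRUE),
    median_em_kg_nonresponder = stats::median(em$n_cells_per_kg[!em$responder], na.rm = TRUE),
    wilcoxon_p = em_test$p
  ), file.path(out_dir, "em_dose_response.csv"))

  # cytokine ratio time courses
  cy <- cytokine_ratio_analysis(trial$cytokines, patients)
  if (!is.null(cy$ratios)) {
    write_csv_exact(cy$ratios[, c("analyte", "timepoint", "day", "ratio",
                                  "ci_lo", "ci_hi", "p")],
                    file.path(out_dir, "cytokine_ratios.csv"))
    rm_ <- ratio_matrix(cy$ratios)
    write_csv_exact(data.frame(analyte = rownames(rm_), rm_,
                               check.names = FALSE),
                    file.path(out_dir, "cytokine_ratio_matrix.csv"))
  }
  n_nonconv <- sum(!vapply(cy$fits, `[[`, TRUE, "converged"))
  if (n_nonconv) note("%d cytokine fit(s) flagged non-converged", n_nonconv)

  # expression
  ex <- normalize_counts(trial$expression, norm_params())
  pre <- ex$samples$timepoint == "pre"
  ex_pre <- subset_experiment(ex, pre)
  kept <- filter_gene_sets(trial$genesets, ex_pre)
  note("gene-set filter kept %d of %d sets", length(kept), length(trial$genesets))
  resp_pre <- ex_pre$samples$responder
  if (sum(resp_pre) >= 2 && sum(!resp_pre) >= 2) {
    genes_tab <- moderated_t_group(ex_pre, "responder")
    write_csv_exact(genes_tab, file.path(out_dir, "genes.csv"))
    if (length(kept)) {
      gs <- gene_set_tests(ex_pre, group = "responder", sets = kept,
                           B = perm_B, seed = derive_seed(config$seed, "permutation"))
      write_csv_exact(gs, file.path(out_dir, "genesets.csv"))
    }
  } else {
    note("pre-infusion expression comparison skipped: fewer than 2 samples per response group")
  }
  macro <- paired_timepoint_lme(ex, set = trial$genesets$macrophage,
                                set_average = TRUE)
  write_csv_exact(macro, file.path(out_dir, "macrophage_pre_vs_progression.csv"))

  # manifest
  files <- list.files(out_dir, recursive = TRUE, full.names = TRUE)
  files <- setdiff(files, file.path(out_dir, "manifest.json"))
  digests <- as.list(tools::md5sum(sort(files)))
  names(digests) <- sub(paste0("^", out_dir, "/?"), "", names(digests))
  cfg_file <- tempfile(fileext = ".yaml")
  write_config(config, cfg_file)
  manifest <- list(
    package_version = as.character(utils::packageVersion("tcrbm")),
    seed = config$seed,
    config_md5 = unname(tools::md5sum(cfg_file)),
    n_patients = nrow(patients),
    stage_counts = list(
      flow_samples_retained = length(unique(doses$patient_id)),
      flow_samples_rejected = nrow(attr(doses, "qc_rejected")),
      cytokine_fits = length(cy$fits),
      gene_sets_kept = length(kept)
    ),
    warnings = warnings_log,
    file_md5 = digests
  )
  unlink(cfg_file)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Subset an expression experiment by sample
#'
#' @param exp an [expression_experiment()].
#' @param idx logical or integer sample index.
#' @return the subsetted experiment (normalized matrix carried along).
#' @export
subset_experiment <- function(exp, idx) {
  out <- exp
  out$counts <- exp$counts[, idx, drop = FALSE]
  out$samples <- exp$samples[idx, , drop = FALSE]
  if (!is.null(exp$norm_log2)) out$norm_log2 <- exp$norm_log2[, idx, drop = FALSE]
  out
}
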