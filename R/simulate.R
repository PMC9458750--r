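#' Simulate a complete synthetic trial dataset
#'
#' Generates a virtual trial with the statistical structure the downstream
#' analyses assume: patient-level clinical covariates and survival, a
#' longitudinal left-censored cytokine panel, product flow-cytometry counts
#' with healthy-donor negative-control noise levels, transgene qPCR expansion
#' series, and a probe-class-annotated expression experiment. Ground-truth
#' generative parameters are stored alongside so recovery tests can compare
#' estimates against them.
#'
#' @param config a [sim_config()].
#' @return object of class `trial_dataset`: a list with elements `patients`,
#'   `cytokines`, `flow_counts`, `noise`, `expansion`, `expression`,
#'   `genesets`, `config`, and `truth`.
#' @examples
#' trial <- simulate_trial(sim_config(n_patients = 12, seed = 1))
#' nrow(trial$patients)
#' @export
simulate_trial <- function(config = sim_config()) {
  validate_config(config)
  set.seed(config$seed)
  patients <- simulate_patients(config)
  cytokines <- simulate_cytokine_panel(patients, config$cytokine_params,
                                       seed = derive_seed(config$seed, "cytokines"))
  flow <- simulate_flow_counts(patients, config$flow_params,
                               seed = derive_seed(config$seed, "flow"))
  expansion <- simulate_expansion_series(patients, config$expansion_params,
                                         seed = derive_seed(config$seed, "expansion"))
  expr <- simulate_expression_experiment(patients, config$expression_params,
                                         seed = derive_seed(config$seed, "expression"))
  out <- list(
    patients = patients[, setdiff(names(patients), c("log_cmax_true"))],
    cytokines = cytokines,
    flow_counts = flow$counts,
    noise = flow$noise,
    expansion = expansion,
    expression = expr,
    genesets = toy_genesets(),
    config = config,
    truth = list(
      log_cmax = stats::setNames(patients$log_cmax_true, patients$patient_id),
      cytokine_params = config$cytokine_params,
      expansion_params = config$expansion_params,
      flow_params = config$flow_params,
      expression_params = config$expression_params,
      survival_params = config$survival_params
    )
  )
  class(out) <- "trial_dataset"
  out
}

#' @method print trial_dataset
#' @export
print.trial_dataset <- function(x, ...) {
  cat("Synthetic TCR T-cell trial dataset\n")
  cat(sprintf("  patients:  %d (%d responders)\n",
              nrow(x$patients), sum(x$patients$responder)))
  cat(sprintf("  cytokines: %d measurements, %d analytes (%.1f%% censored)\n",
              nrow(x$cytokines), length(unique(x$cytokines$analyte)),
              100 * mean(x$cytokines$censored)))
  cat(sprintf("  flow:      %d gated rows over %d samples\n",
              nrow(x$flow_counts), length(unique(x$flow_counts$sample_id))))
  cat(sprintf("  expansion: %d qPCR points\n", nrow(x$expansion)))
  cat(sprintf("  expression: %d probes x %d samples\n",
              nrow(x$expression$counts), ncol(x$expression$counts)))
  invisible(x)
}

#' Simulate the patient-level clinical table
#'
#' Cohort membership is multinomial on `cohort_weights`; lymphodepletion is
#' cohort-determined (1-2 standard fluCy, 3 cyclophosphamide-only, 4 reduced
#' fluCy). Transduced cell dose is log-normal around 3e9 clamped to
#' [1e9, 6e9]. Latent log Cmax follows the expansion model; responder status
#' is a logistic function of log Cmax, so dose/kg and standard LDR raise
#' response probability through expansion. PFS and OS are exponential with
#' log-hazard linear in log Cmax and administrative censoring.
#'
#' @param config a [sim_config()].
#' @return data.frame with one row per patient (includes the latent
#'   `log_cmax_true` column used by downstream generators).
#' @export
simulate_patients <- function(config) {
  n <- config$n_patients
  ep <- config$expansion_params
  sp <- config$survival_params
  rm_ <- config$responder_model
  cohort <- sample(1:4, n, replace = TRUE, prob = config$cohort_weights)
  ldr <- c("standard_fluCy", "standard_fluCy", "cy_only", "reduced_fluCy")[cohort]
  weight_kg <- pmax(40, stats::rlnorm(n, log(70), 0.22))
  dose <- pmin(6e9, pmax(1e9, stats::rlnorm(n, log(3e9), 0.4)))
  log_cmax <- ep$alpha +
    ep$beta_dose * (log(dose / weight_kg) - log(ep$ref_dose_per_kg)) +
    ep$ldr_effect[ldr] +
    stats::rnorm(n, 0, ep$noise_sd)
  p_resp <- stats::plogis(rm_$intercept + rm_$slope * (log_cmax - rm_$cmax_center))
  responder <- stats::runif(n) < p_resp
  best_response <- ifelse(responder,
                          ifelse(stats::runif(n) < 0.1, "CR", "PR"),
                          sample(c("SD", "PD", "NE"), n, replace = TRUE,
                                 prob = c(0.6, 0.3, 0.1)))
  pfs_rate <- log(2) / sp$pfs_median_days *
    exp(sp$log_hr_cmax_pfs * (log_cmax - sp$cmax_center))
  os_rate <- log(2) / sp$os_median_days *
    exp(sp$log_hr_cmax_os * (log_cmax - sp$cmax_center))
  pfs_t <- stats::rexp(n, pfs_rate)
  os_t <- stats::rexp(n, os_rate)
  data.frame(
    patient_id = sprintf("P%03d", seq_len(n)),
    cohort = cohort,
    ldr = ldr,
    weight_kg = round(weight_kg, 1),
    transduced_cell_dose = round(dose),
    responder = responder,
    best_response = best_response,
    pfs_days = round(pmin(pfs_t, sp$horizon_pfs), 1),
    pfs_event = pfs_t <= sp$horizon_pfs,
    os_days = round(pmin(os_t, sp$horizon_os), 1),
    os_event = os_t <= sp$horizon_os,
    log_cmax_true = log_cmax,
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

#' Simulate the longitudinal serum cytokine panel
#'
#' Concentrations are drawn as `exp` of a normal linear mixed model:
#' log value = baseline + time effect + responder effect x responder +
#' subject intercept (SD `sigma_b`) + residual (SD `sigma_e`). Draws below
#' the analyte LLOQ are flagged censored and reported at the LLOQ.
#'
#' @param patients patient table with `patient_id` and `responder`.
#' @param cytokine_params per-analyte parameter list (see [sim_config()]).
#' @param timepoints subset of [cytokine_grid()] labels; defaults to the full
#'   study grid.
#' @param seed integer seed.
#' @return long data.frame: patient_id, analyte, timepoint, day, value, lloq,
#'   censored.
#' @export
simulate_cytokine_panel <- function(patients, cytokine_params,
                                    timepoints = cytokine_grid()$timepoint,
                                    seed = 1L) {
  grid <- cytokine_grid()
  if (!all(timepoints %in% grid$timepoint))
    stop_config("timepoints must belong to the study grid")
  grid <- grid[match(timepoints, grid$timepoint), , drop = FALSE]
  set.seed(seed)
  n <- nrow(patients)
  out <- vector("list", length(cytokine_params))
  for (i in seq_along(cytokine_params)) {
    a <- names(cytokine_params)[i]
    p <- cytokine_params[[i]]
    b <- stats::rnorm(n, 0, p$sigma_b)
    mu <- outer(as.numeric(patients$responder), p$responder_effect[grid$timepoint]) +
      matrix(p$time_effect[grid$timepoint], n, nrow(grid), byrow = TRUE) +
      p$baseline + b
    logy <- mu + stats::rnorm(length(mu), 0, p$sigma_e)
    val <- exp(logy)
    cens <- val < p$lloq
    val[cens] <- p$lloq
    out[[i]] <- data.frame(
      patient_id = rep(patients$patient_id, times = nrow(grid)),
      analyte = a,
      timepoint = rep(grid$timepoint, each = n),
      day = rep(grid$day, each = n),
      value = as.vector(val),
      lloq = p$lloq,
      censored = as.vector(cens),
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  row.names(res) <- NULL
  res
}

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha)
  g / sum(g)
}

#' Simulate gated product flow-cytometry counts and negative-control noise
#'
#' One product sample per patient, measured in two panels (Pheno1, Pheno2).
#' Each panel carries a viable CD3 count and the CD4/CD8 Pentamer+ parent
#' gates; memory subsets (Naive/TSCM/CM/EM/TEMRA) are children of each
#' pentamer parent in Pheno1. Responder products are EM-enriched in the CD8
#' compartment per `flow_params`. Healthy-donor negative-control staining
#' yields the per-parent noise levels (maximum observed frequency).
#'
#' @param patients patient table.
#' @param flow_params see [sim_config()].
#' @param seed integer seed.
#' @return list with `counts` (long data.frame: sample_id, panel, population,
#'   parent, count, freq_of_parent) and `noise` (population,
#'   max_negative_control_freq).
#' @export
simulate_flow_counts <- function(patients, flow_params, seed = 1L) {
  set.seed(seed)
  fp <- flow_params
  phenos <- c("Naive", "TSCM", "CM", "EM", "TEMRA")
  rows <- list()
  for (i in seq_len(nrow(patients))) {
    pid <- patients$patient_id[i]
    sid <- paste0(pid, "_product")
    resp <- patients$responder[i]
    cd8_simplex <- if (resp) fp$cd8_simplex_responder else fp$cd8_simplex_nonresponder
    for (panel in c("Pheno1", "Pheno2")) {
      viable <- round(stats::rlnorm(1, fp$viable_cd3_meanlog, fp$viable_cd3_sdlog))
      n_cd4 <- round(viable * 0.55)
      n_cd8 <- round(viable * 0.35)
      cd4_pent <- stats::rbinom(1, n_cd4, fp$cd4_pent_freq)
      cd8_pent <- stats::rbinom(1, n_cd8, fp$cd8_pent_freq)
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = sid, panel = panel,
        population = c("CD3", "CD4Pent", "CD8Pent"),
        parent = c(NA, "CD3", "CD3"),
        count = c(viable, cd4_pent, cd8_pent),
        freq_of_parent = c(NA, cd4_pent / n_cd4, cd8_pent / n_cd8),
        stringsAsFactors = FALSE
      )
      if (panel == "Pheno1") {
        w8 <- rdirichlet1(fp$dirichlet_conc * cd8_simplex)
        w4 <- rdirichlet1(fp$dirichlet_conc * fp$cd4_simplex)
        k8 <- as.vector(stats::rmultinom(1, cd8_pent, w8))
        k4 <- as.vector(stats::rmultinom(1, cd4_pent, w4))
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = sid, panel = panel,
          population = c(paste0("CD8Pent_", phenos), paste0("CD4Pent_", phenos)),
          parent = rep(c("CD8Pent", "CD4Pent"), each = 5),
          count = c(k8, k4),
          freq_of_parent = c(if (cd8_pent > 0) k8 / cd8_pent else rep(NA, 5),
                             if (cd4_pent > 0) k4 / cd4_pent else rep(NA, 5)),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  counts <- do.call(rbind, rows)
  row.names(counts) <- NULL
  neg <- matrix(stats::rbeta(2 * fp$n_negative_controls, 1.2, 1.2 / fp$negative_control_rate),
                nrow = fp$n_negative_controls)
  noise <- data.frame(
    population = c("CD4Pent", "CD8Pent"),
    max_negative_control_freq = apply(neg, 2, max),
    stringsAsFactors = FALSE
  )
  list(counts = counts, noise = noise)
}

#' Simulate transgene qPCR expansion series
#'
#' Subject-level log Cmax comes from the latent expansion model stored in the
#' patient table (dose/kg and LDR effects plus noise); the time course is
#' Cmax times a fixed rise/decay shape on [expansion_grid()] with
#' per-timepoint multiplicative log-normal noise. Values below the detection
#' floor are reported as 0.
#'
#' @param patients patient table containing `log_cmax_true`.
#' @param expansion_params see [sim_config()].
#' @param seed integer seed.
#' @return data.frame: patient_id, day, copies_per_ug.
#' @export
simulate_expansion_series <- function(patients, expansion_params, seed = 1L) {
  set.seed(seed)
  ep <- expansion_params
  days <- expansion_grid()
  n <- nrow(patients)
  logc <- outer(patients$log_cmax_true, log(ep$shape), `+`) +
    matrix(stats::rnorm(n * length(days), 0, ep$obs_noise_sd), n)
  copies <- exp(logc)
  copies[copies < ep$lod] <- 0
  out <- data.frame(
    patient_id = rep(patients$patient_id, times = length(days)),
    day = rep(days, each = n),
    copies_per_ug = as.vector(copies),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$patient_id, out$day), ]
  row.names(out) <- NULL
  out
}

#' Simulate a probe-class-annotated expression experiment
#'
#' Endogenous gene log2 means are normal; counts are negative binomial around
#' `2^(mean + lane effect + biology shifts)`. Housekeeping probes are
#' high-expressed and shift-free, positive probes follow a fixed titration
#' ladder, negative probes are low background. Progression samples carry the
#' configured macrophage-set log2 down-shift; non-responder pre-infusion
#' samples carry the IFN-set up-shift. The per-sample lane effect applies to
#' all probe classes and is what normalization removes.
#'
#' @param patients patient table.
#' @param expression_params see [sim_config()].
#' @param seed integer seed.
#' @return an [expression_experiment()] with raw counts.
#' @export
simulate_expression_experiment <- function(patients, expression_params, seed = 1L) {
  set.seed(seed)
  xp <- expression_params
  sets <- toy_genesets()
  set_genes <- unique(unlist(sets))
  if (xp$n_genes < max(lengths(sets)))
    stop_config("n_genes must be >= the largest bundled gene set")
  if (xp$n_genes < length(set_genes))
    stop_config("n_genes must cover the %d bundled gene-set symbols", length(set_genes))
  genes <- c(set_genes,
             sprintf("GENE%03d", seq_len(xp$n_genes - length(set_genes))))
  hk <- c("ACTB", "GAPDH", "TUBB", "POLR2A", "TBP", "RPL19", "SDHA", "HPRT1",
          "GUSB", "PGK1", "PPIA", "TFRC")[seq_len(xp$n_housekeeping)]
  pos <- sprintf("POS_%s", LETTERS[seq_len(xp$n_positive)])
  neg <- sprintf("NEG_%s", LETTERS[seq_len(xp$n_negative)])
  probe <- data.frame(
    gene = c(genes, hk, pos, neg),
    probe_class = c(rep("Endogenous", length(genes)),
                    rep("Housekeeping", length(hk)),
                    rep("Positive", length(pos)),
                    rep("Negative", length(neg))),
    panel = xp$panel,
    stringsAsFactors = FALSE
  )
  n_pre <- min(xp$n_pre, nrow(patients))
  pre_pat <- patients$patient_id[seq_len(n_pre)]
  prog_pool <- c(pre_pat[seq_len(min(xp$n_paired, n_pre))],
                 setdiff(patients$patient_id, pre_pat))
  prog_pat <- prog_pool[seq_len(min(xp$n_progression, length(prog_pool)))]
  samples <- rbind(
    data.frame(patient_id = pre_pat, timepoint = "pre", stringsAsFactors = FALSE),
    data.frame(patient_id = prog_pat, timepoint = "progression", stringsAsFactors = FALSE)
  )
  samples$sample_id <- paste0(samples$patient_id, "_", samples$timepoint)
  samples$responder <- patients$responder[match(samples$patient_id, patients$patient_id)]
  samples <- samples[, c("sample_id", "patient_id", "timepoint", "responder")]

  mu_gene <- stats::rnorm(length(genes), xp$gene_meanlog2, xp$gene_sdlog2)
  names(mu_gene) <- genes
  mu_hk <- stats::rnorm(length(hk), 10, 0.5)
  mu_pos <- log2(32 * 4^seq(xp$n_positive - 1, 0))  # titration ladder
  mu_neg <- rep(log2(2), length(neg))
  lane <- stats::rnorm(nrow(samples), 0, xp$lane_sdlog2)

  macro <- intersect(sets$macrophage, genes)
  ifn <- intersect(sets$IFN_downstream, genes)
  counts <- matrix(0L, nrow(probe), nrow(samples),
                   dimnames = list(probe$gene, samples$sample_id))
  for (s in seq_len(nrow(samples))) {
    mu <- c(mu_gene, mu_hk, mu_pos, mu_neg)
    if (samples$timepoint[s] == "progression")
      mu[macro] <- mu[macro] + xp$macrophage_shift
    if (samples$timepoint[s] == "pre" && !samples$responder[s])
      mu[ifn] <- mu[ifn] + xp$ifn_shift
    m <- 2^(mu + lane[s])
    counts[, s] <- stats::rnbinom(length(m), size = xp$dispersion, mu = m)
  }
  expression_experiment(counts, probe, samples)
}

#' Bundled toy gene-set collection
#'
#' A small fixed collection standing in for external KEGG/GO/REACTOME/MSigDB
#' resources; labelled synthetic. Includes the macrophage, IFN-downstream and
#' antigen-presentation sets the pipeline's set-level analyses target.
#'
#' @return named list of character vectors of gene symbols.
#' @export
toy_genesets <- function() {
  list(
    macrophage = c("CD163", "CD68", "CD84", "MSR1", "MRC1", "CSF1R"),
    IFN_downstream = c("STAT1", "STAT2", "IRF7", "MX1", "OAS1", "ISG15",
                       "IFI6", "IFIT1"),
    antigen_presentation = c("HLA-A", "HLA-B", "B2M", "TAP1", "TAP2", "PSMB9"),
    tcell_cytotoxicity = c("CD8A", "GZMB", "PRF1", "IFNG", "CD3E", "NKG7"),
    cell_cycle = c("MKI67", "CCNB1", "CDK1", "PLK1", "TOP2A", "BUB1"),
    tgfb_wnt = c("TGFB1", "TGFB2", "WNT5A", "CTNNB1", "SMAD3", "AXIN2")
  )
}
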