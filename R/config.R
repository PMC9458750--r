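#' Serum cytokine sampling grid
#'
#' The longitudinal schedule on which serum cytokines are drawn and modelled:
#' baseline (7 days before lymphodepletion), day 0 pre-infusion, days 1, 4, 7
#' and weeks 2, 3, 4, 6, 8 post-infusion. Timepoints are treated as
#' categorical levels throughout.
#'
#' @return data.frame with columns `timepoint` (ordered factor labels) and
#'   `day` (numeric study day; baseline coded -7).
#' @export
cytokine_grid <- function() {
  data.frame(
    timepoint = c("baseline", "d0", "d1", "d4", "d7",
                  "wk2", "wk3", "wk4", "wk6", "wk8"),
    day = c(-7, 0, 1, 4, 7, 14, 21, 28, 42, 56),
    stringsAsFactors = FALSE
  )
}

#' Transgene qPCR sampling days
#'
#' Days at which vector copies per microgram of genomic DNA are sampled in the
#' simulated trial (day 0 infusion through week 8).
#' @return numeric vector of days.
#' @export
expansion_grid <- function() c(0, 4, 7, 14, 28, 42, 56)

default_cytokine_params <- function() {
  tp <- cytokine_grid()$timepoint
  mk <- function(baseline, time_eff, resp_eff, sigma_b = 0.5, sigma_e = 0.6,
                 lloq = exp(baseline - 1.2)) {
    names(time_eff) <- names(resp_eff) <- tp
    list(baseline = baseline, time_effect = time_eff,
         responder_effect = resp_eff, sigma_b = sigma_b, sigma_e = sigma_e,
         lloq = lloq)
  }
  # time_effect: common post-lymphodepletion / post-infusion course.
  # responder_effect: extra log-elevation in responders per timepoint;
  # IL-15 is elevated already at day 0 (pre-infusion, post-LDR), the
  # inflammatory markers peak around days 3-7.
  list(
    "IL-15"   = mk(log(2.5),
                   c(0, .8, 1.0, .6, .4, .2, .1, 0, 0, 0),
                   c(.3, .7, .6, .5, .4, .3, .2, .1, 0, 0)),
    "IFNg"    = mk(log(5),
                   c(0, .1, .4, .8, .5, .2, .1, 0, 0, 0),
                   c(0, 0, .5, 1.5, 1.2, .6, .3, .2, 0, 0)),
    "IL-6"    = mk(log(3),
                   c(0, .2, .5, .8, .5, .2, .1, 0, 0, 0),
                   c(0, 0, .5, 1.2, 1.0, .5, .2, .1, 0, 0)),
    "IL-2Ra"  = mk(log(500),
                   c(0, .1, .3, .6, .6, .4, .2, .1, 0, 0),
                   c(0, .2, .6, 1.2, 1.0, .6, .4, .3, .1, 0)),
    "GM-CSF"  = mk(log(0.4),
                   c(0, 0, .3, .6, .4, .1, 0, 0, 0, 0),
                   c(0, 0, .4, 1.0, .8, .3, 0, 0, 0, 0),
                   lloq = exp(log(0.4) + 0.5)),
    "IL-17A"  = mk(log(0.6),
                   c(0, 0, .2, .5, .3, .1, 0, 0, 0, 0),
                   c(0, 0, .3, .8, .6, .2, 0, 0, 0, 0),
                   lloq = exp(log(0.6) + 0.5)),
    "IL-7"    = mk(log(4),
                   c(0, .6, .8, .6, .4, .2, .1, 0, 0, 0),
                   rep(0, 10)),
    "TNFa"    = mk(log(2.5),
                   c(0, .1, .3, .5, .3, .1, 0, 0, 0, 0),
                   c(0, 0, .2, .5, .4, .2, .1, 0, 0, 0)),
    "IL-8"    = mk(log(8),
                   c(0, .2, .4, .5, .3, .1, 0, 0, 0, 0),
                   c(0, 0, .2, .4, .3, .1, 0, 0, 0, 0)),
    "IL-10"   = mk(log(1.5),
                   c(0, .1, .3, .4, .2, .1, 0, 0, 0, 0),
                   c(0, 0, .2, .4, .3, .1, 0, 0, 0, 0))
  )
}

default_flow_params <- function() {
  list(
    # memory composition of CD8+Pentamer+ cells in the infused product;
    # responders are effector-memory enriched (~28% vs ~12% EM), mirroring
    # the reported product phenotype difference.
    cd8_simplex_responder    = c(Naive = .15, TSCM = .12, CM = .25, EM = .28, TEMRA = .20),
    cd8_simplex_nonresponder = c(Naive = .22, TSCM = .15, CM = .28, EM = .12, TEMRA = .23),
    cd4_simplex              = c(Naive = .25, TSCM = .10, CM = .35, EM = .20, TEMRA = .10),
    dirichlet_conc = 60,
    cd4_pent_freq = 0.05,    # frequency of Pentamer+ among CD3+CD4+
    cd8_pent_freq = 0.20,    # frequency of Pentamer+ among CD3+CD8+
    viable_cd3_meanlog = log(4e4),
    viable_cd3_sdlog = 0.5,
    n_negative_controls = 6,
    negative_control_rate = 3e-4  # per-donor Pentamer+ background frequency scale
  )
}

default_expansion_params <- function() {
  list(
    alpha = log(2e4),          # log Cmax (copies/ug) at reference dose, non-standard LDR
    beta_dose = 1.0,           # per unit log(dose per kg / reference)
    ref_dose_per_kg = 4e7,
    ldr_effect = c(standard_fluCy = 1.0, cy_only = 0, reduced_fluCy = 0.4),
    noise_sd = 0.8,            # subject-level log Cmax noise
    obs_noise_sd = 0.25,       # per-timepoint multiplicative noise (log scale)
    # fixed rise/decay shape relative to Cmax, on expansion_grid() days
    shape = c(0.02, 0.55, 1.0, 0.75, 0.45, 0.28, 0.18),
    lod = 50                   # qPCR detection floor (copies/ug)
  )
}

default_expression_params <- function() {
  list(
    n_genes = 200,             # endogenous probes
    n_housekeeping = 10,
    n_positive = 6,
    n_negative = 8,
    macrophage_shift = -1,     # log2 shift of macrophage-set genes at progression
    ifn_shift = 1,             # log2 shift of IFN-set genes in non-responder pre samples
    dispersion = 15,           # negative-binomial size
    lane_sdlog2 = 0.35,        # per-sample global (lane) scale, removed by normalization
    gene_sdlog2 = 1.5,         # spread of endogenous log2 means
    gene_meanlog2 = 7,
    n_pre = 10,
    n_progression = 5,
    n_paired = 3,
    panel = "immune"
  )
}

default_survival_params <- function() {
  list(
    pfs_median_days = 105,     # baseline PFS median (~15 weeks)
    os_median_days = 500,
    log_hr_cmax_pfs = -0.5,    # log hazard ratio per unit log Cmax (centred)
    log_hr_cmax_os = -0.35,
    cmax_center = 10.7,        # centring constant for log Cmax
    horizon_pfs = 730,         # administrative censoring, days
    horizon_os = 1095
  )
}

#' Simulation configuration for a synthetic TCR T-cell trial
#'
#' Builds the full parameter set for [simulate_trial()]. Defaults emulate the
#' study conditions of the source trial: 45 infused patients in four cohorts
#' (12/13/5/15), cohorts 1-2 with standard fludarabine+cyclophosphamide
#' lymphodepletion, cohort 3 cyclophosphamide-only, cohort 4 reduced
#' fludarabine+cyclophosphamide; transduced-cell dose in [1e9, 6e9] (target
#' 5e9); dose/kg- and LDR-dependent expansion; responder-by-time cytokine
#' elevation with left-censoring at analyte LLOQs; effector-memory-enriched
#' responder product phenotype; probe-class-structured expression counts with
#' macrophage-set down-shift at progression and IFN-set up-shift in
#' non-responder pre-infusion samples; exponential survival with log-hazard
#' linear in log Cmax.
#'
#' @param n_patients number of infused (mITT) patients.
#' @param cohort_weights probabilities over the 4 cohorts; must sum to 1.
#' @param seed integer seed controlling all generators.
#' @param cytokine_params,expansion_params,flow_params,expression_params,survival_params
#'   per-domain parameter lists; any element supplied here overrides the
#'   corresponding default.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_patients = 45,
                       cohort_weights = c(12, 13, 5, 15) / 45,
                       seed = 1L,
                       cytokine_params = list(),
                       expansion_params = list(),
                       flow_params = list(),
                       expression_params = list(),
                       survival_params = list()) {
  cfg <- list(
    n_patients = as.integer(n_patients),
    cohort_weights = cohort_weights,
    seed = as.integer(seed),
    cytokine_params = utils::modifyList(default_cytokine_params(), cytokine_params),
    expansion_params = utils::modifyList(default_expansion_params(), expansion_params),
    flow_params = utils::modifyList(default_flow_params(), flow_params),
    expression_params = utils::modifyList(default_expression_params(), expression_params),
    survival_params = utils::modifyList(default_survival_params(), survival_params),
    responder_model = list(intercept = -0.7, slope = 1.2, cmax_center = 10.7)
  )
  class(cfg) <- "sim_config"
  validate_config(cfg)
  cfg
}

#' Validate a simulation configuration
#'
#' Checks the structural invariants: positive SDs and LLOQs, phenotype
#' compositions and cohort weights summing to 1, probe-class counts, and
#' non-negative shape values.
#'
#' @param cfg a `sim_config`.
#' @return `cfg`, invisibly; errors with a configuration message otherwise.
#' @export
validate_config <- function(cfg) {
  if (cfg$n_patients < 1) stop_config("n_patients must be >= 1")
  w <- cfg$cohort_weights
  if (length(w) != 4 || any(w < 0) || abs(sum(w) - 1) > 1e-8)
    stop_config("cohort_weights must be 4 non-negative probabilities summing to 1")
  for (a in names(cfg$cytokine_params)) {
    p <- cfg$cytokine_params[[a]]
    if (p$sigma_b < 0 || p$sigma_e <= 0)
      stop_config("cytokine '%s': SDs must be positive", a)
    if (p$lloq <= 0) stop_config("cytokine '%s': LLOQ must be > 0", a)
    if (length(p$time_effect) != 10 || length(p$responder_effect) != 10)
      stop_config("cytokine '%s': effect vectors must match the 10-point grid", a)
  }
  fp <- cfg$flow_params
  for (nm in c("cd8_simplex_responder", "cd8_simplex_nonresponder", "cd4_simplex")) {
    s <- fp[[nm]]
    if (any(s < 0) || abs(sum(s) - 1) > 1e-8)
      stop_config("flow_params$%s must be a probability simplex summing to 1", nm)
  }
  ep <- cfg$expansion_params
  if (ep$noise_sd < 0 || ep$obs_noise_sd < 0)
    stop_config("expansion noise SDs must be >= 0")
  if (length(ep$shape) != length(expansion_grid()))
    stop_config("expansion shape must match expansion_grid()")
  xp <- cfg$expression_params
  if (xp$n_genes < 1 || xp$n_housekeeping < 1 || xp$n_positive < 1 || xp$n_negative < 1)
    stop_config("expression probe-class counts must be >= 1")
  if (xp$dispersion <= 0) stop_config("expression dispersion must be > 0")
  sp <- cfg$survival_params
  if (sp$pfs_median_days <= 0 || sp$os_median_days <= 0)
    stop_config("survival medians must be > 0")
  invisible(cfg)
}

#' Read / write a simulation configuration as YAML
#'
#' Cytokine effect vectors are stored as named lists; [read_config()] restores
#' the `sim_config` class and re-validates.
#'
#' @param cfg a `sim_config`.
#' @param path YAML file path.
#' @return `read_config()` returns a `sim_config`.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  raw$cytokine_params <- lapply(raw$cytokine_params, function(p) {
    p$time_effect <- unlist(p$time_effect)
    p$responder_effect <- unlist(p$responder_effect)
    p
  })
  for (nm in c("cd8_simplex_responder", "cd8_simplex_nonresponder", "cd4_simplex"))
    raw$flow_params[[nm]] <- unlist(raw$flow_params[[nm]])
  raw$expansion_params$ldr_effect <- unlist(raw$expansion_params$ldr_effect)
  raw$expansion_params$shape <- unlist(raw$expansion_params$shape)
  cfg <- raw
  class(cfg) <- "sim_config"
  validate_config(cfg)
  cfg
}
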