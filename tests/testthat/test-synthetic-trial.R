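test_that("simulation is deterministic under a fixed seed", {
  cfg <- sim_config(n_patients = 45, seed = 7)
  t1 <- simulate_trial(cfg)
  t2 <- simulate_trial(cfg)
  expect_identical(t1, t2)
  t3 <- simulate_trial(sim_config(n_patients = 45, seed = 8))
  expect_false(identical(t1$patients, t3$patients))
})

test_that("one patient record per subject, linked across all data domains", {
  tr <- simulate_trial(sim_config(n_patients = 45, seed = 3))
  p <- tr$patients
  expect_equal(nrow(p), 45)
  expect_equal(anyDuplicated(p$patient_id), 0)
  expect_setequal(unique(tr$cytokines$patient_id), p$patient_id)
  expect_setequal(unique(sub("_product$", "", tr$flow_counts$sample_id)),
                  p$patient_id)
  expect_setequal(unique(tr$expansion$patient_id), p$patient_id)
  expect_true(all(tr$expression$samples$patient_id %in% p$patient_id))
})

test_that("patient-level invariants hold", {
  tr <- simulate_trial(sim_config(n_patients = 60, seed = 11))
  p <- tr$patients
  expect_true(all(p$transduced_cell_dose >= 1e9 & p$transduced_cell_dose <= 6e9))
  expect_true(all(p$weight_kg >= 40))
  expect_identical(p$responder, p$best_response %in% c("CR", "PR"))
  expect_true(all(p$pfs_days >= 0 & p$os_days >= 0))
  expect_true(all(p$ldr[p$cohort %in% 1:2] == "standard_fluCy"))
  expect_true(all(p$ldr[p$cohort == 3] == "cy_only"))
  expect_true(all(p$ldr[p$cohort == 4] == "reduced_fluCy"))
})

test_that("configuration invariants are enforced", {
  expect_error(sim_config(cohort_weights = c(0.5, 0.5, 0.5, 0.5)), "summing to 1")
  expect_error(sim_config(flow_params = list(
    cd4_simplex = c(Naive = .5, TSCM = .2, CM = .2, EM = .2, TEMRA = .2))),
    "simplex")
  expect_error(sim_config(cytokine_params = list(
    "IL-15" = utils::modifyList(default_cytokine_params()[["IL-15"]],
                                list(sigma_e = -1)))),
    "positive")
  expect_error(sim_config(cytokine_params = list(
    "IL-15" = utils::modifyList(default_cytokine_params()[["IL-15"]],
                                list(lloq = 0)))),
    "LLOQ")
})

test_that("noise-free cytokines equal the exponentiated fixed-effect curve", {
  pats <- data.frame(patient_id = c("A", "B"), responder = c(TRUE, FALSE))
  params <- list("X" = list(
    baseline = 1,
    time_effect = stats::setNames(seq(0, 0.9, by = 0.1), cytokine_grid()$timepoint),
    responder_effect = stats::setNames(rep(0.5, 10), cytokine_grid()$timepoint),
    sigma_b = 1e-12, sigma_e = 1e-12, lloq = 1e-6))
  cy <- simulate_cytokine_panel(pats, params, seed = 1)
  grid <- cytokine_grid()
  expected <- exp(1 + grid$day * 0 + seq(0, 0.9, by = 0.1)[match(cy$timepoint, grid$timepoint)] +
                    0.5 * (cy$patient_id == "A"))
  expect_equal(cy$value, expected, tolerance = 1e-6)
  expect_false(any(cy$censored))
})

test_that("an LLOQ above the generative distribution censors everything", {
  pats <- data.frame(patient_id = sprintf("P%02d", 1:20), responder = FALSE)
  params <- list("X" = list(
    baseline = 1, time_effect = stats::setNames(rep(0, 10), cytokine_grid()$timepoint),
    responder_effect = stats::setNames(rep(0, 10), cytokine_grid()$timepoint),
    sigma_b = 0.5, sigma_e = 0.5, lloq = exp(1 + 10)))
  cy <- simulate_cytokine_panel(pats, params, seed = 2)
  expect_true(all(cy$censored))
  expect_true(all(cy$value == cy$lloq))
})

test_that("empirical censoring fraction matches the normal-tail closed form", {
  # P(log Y < log LLOQ) = Phi((log LLOQ - mu) / sqrt(sigma_b^2 + sigma_e^2))
  sb <- 0.5; se <- 0.7; mu <- 1; lloq <- exp(0.6)
  pats <- data.frame(patient_id = sprintf("P%05d", 1:10000), responder = FALSE)
  params <- list("X" = list(
    baseline = mu,
    time_effect = stats::setNames(rep(0, 10), cytokine_grid()$timepoint),
    responder_effect = stats::setNames(rep(0, 10), cytokine_grid()$timepoint),
    sigma_b = sb, sigma_e = se, lloq = lloq))
  cy <- simulate_cytokine_panel(pats, params, timepoints = "d0", seed = 5)
  expect_equal(nrow(cy), 10000)
  theo <- pnorm((log(lloq) - mu) / sqrt(sb^2 + se^2))
  expect_lt(abs(mean(cy$censored) - theo), 0.03)
})

test_that("expression counts are valid and carry all probe classes and shifts", {
  tr <- simulate_trial(sim_config(n_patients = 20, seed = 9))
  ex <- tr$expression
  expect_true(all(ex$counts >= 0))
  expect_true(all(ex$counts == round(ex$counts)))
  expect_setequal(unique(ex$genes$probe_class),
                  c("Endogenous", "Housekeeping", "Positive", "Negative"))
  expect_error(simulate_expression_experiment(
    tr$patients, utils::modifyList(default_expression_params(), list(n_genes = 3)),
    seed = 1), "largest bundled gene set|cover")
})

test_that("configured macrophage shift is recovered by the paired set LME", {
  # large-sample parameter recovery of the -1 log2 progression shift
  ests <- vapply(1:8, function(s) {
    cfg <- sim_config(n_patients = 40, seed = 100 + s,
                      expression_params = list(n_pre = 20, n_progression = 20,
                                               n_paired = 20, macrophage_shift = -1))
    tr <- simulate_trial(cfg)
    ex <- normalize_counts(tr$expression)
    paired_timepoint_lme(ex, set = toy_genesets()$macrophage,
                         set_average = TRUE)$estimate
  }, 0)
  expect_lt(abs(mean(ests) - (-1)), 0.2)
})

test_that("zero shift parameters give null pre-vs-progression set effects", {
  ps <- vapply(1:12, function(s) {
    cfg <- sim_config(n_patients = 30, seed = 300 + s,
                      expression_params = list(macrophage_shift = 0, ifn_shift = 0,
                                               n_pre = 12, n_progression = 8,
                                               n_paired = 6))
    tr <- simulate_trial(cfg)
    ex <- normalize_counts(tr$expression)
    paired_timepoint_lme(ex, set = toy_genesets()$macrophage,
                         set_average = TRUE)$p
  }, 0)
  # null p-values should not pile up near zero
  expect_gt(mean(ps > 0.05), 0.5)
  expect_gt(min(ps), 1e-4)
})

test_that("generated tables round-trip through the CSV/RCC writers losslessly", {
  tr <- simulate_trial(sim_config(n_patients = 10, seed = 21))
  dir <- withr::local_tempdir()
  write_trial(tr, dir)
  back <- read_trial(dir)
  for (tab in c("patients", "cytokines", "flow_counts", "noise", "expansion")) {
    expect_identical(dim(back[[tab]]), dim(tr[[tab]]))
    for (cl in names(tr[[tab]])) {
      expect_equal(back[[tab]][[cl]], tr[[tab]][[cl]], tolerance = 0,
                   label = paste(tab, cl))
    }
  }
  expect_identical(unname(back$expression$counts[rownames(tr$expression$counts),
                                                 colnames(tr$expression$counts)]),
                   unname(tr$expression$counts))
  expect_identical(back$genesets[names(tr$genesets)], tr$genesets)
})

test_that("null responder effects give LME ratio CIs that cover 1", {
  # IL-7 carries a zero responder effect by default; over replicates the d4
  # responder/non-responder ratio CI should cover 1 at roughly nominal rate
  covered <- vapply(1:100, function(s) {
    set.seed(7000 + s)
    pats <- data.frame(patient_id = sprintf("P%02d", 1:40),
                       responder = rep(c(TRUE, FALSE), 20))
    cy <- simulate_cytokine_panel(pats, default_cytokine_params()["IL-7"],
                                  seed = 7000 + s)
    cy$responder <- pats$responder[match(cy$patient_id, pats$patient_id)]
    cy$timepoint <- factor(cy$timepoint, levels = cytokine_grid()$timepoint)
    fit <- fit_censored_lme(cy)
    rt <- suppressWarnings(wald_ratio_timecourse(fit))
    r <- rt[rt$timepoint == "d4", ]
    r$ci_lo <= 1 && 1 <= r$ci_hi
  }, TRUE)
  expect_gte(mean(covered), 0.90)
})
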