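test_that("RCC files round-trip a simulated experiment", {
  cfg <- sim_config(n_patients = 8, seed = 31,
                    expression_params = list(n_genes = 60, n_pre = 5,
                                             n_progression = 3, n_paired = 2))
  tr <- simulate_trial(cfg)
  dir <- withr::local_tempdir()
  for (s in colnames(tr$expression$counts))
    write_rcc(tr$expression, s, file.path(dir, paste0(s, ".rcc")))
  back <- read_rcc_dir(dir, tr$expression$samples)
  expect_identical(back$counts[rownames(tr$expression$counts),
                               colnames(tr$expression$counts)],
                   tr$expression$counts)
  expect_identical(back$genes$probe_class[match(tr$expression$genes$gene,
                                                back$genes$gene)],
                   tr$expression$genes$probe_class)
})

test_that("RCC parsing validates sections and counts, deferring class checks", {
  dir <- withr::local_tempdir()
  # a file without Negative probes loads, normalization later errors
  ex <- make_toy_exp()
  keep <- ex$genes$probe_class != "Negative"
  ex2 <- expression_experiment(ex$counts[keep, , drop = FALSE],
                               ex$genes[keep, ], ex$samples)
  f <- file.path(dir, "s1.rcc")
  write_rcc(ex2, "s1", f)
  parsed <- read_rcc(f)
  expect_false("Negative" %in% parsed$codes$probe_class)
  expect_error(normalize_counts(ex2), "Negative")
  # malformed count names the probe
  lines <- readLines(f)
  lines[grep("^Endogenous,E1", lines)] <- "Endogenous,E1,SYN_E1,NA"
  writeLines(lines, file.path(dir, "bad.rcc"))
  expect_error(read_rcc(file.path(dir, "bad.rcc")), "E1")
  # missing Code_Summary is a parse error
  writeLines(lines[seq_len(grep("<Code_Summary>", lines) - 1)],
             file.path(dir, "trunc.rcc"))
  expect_error(read_rcc(file.path(dir, "trunc.rcc")), "Code_Summary")
})

test_that("normalization reproduces the hand-computed two-sample pipeline", {
  ex <- make_toy_exp()
  nx <- normalize_counts(ex, norm_params(round_values = FALSE, take_log = FALSE))
  # positives {100,100},{400,400}: geomeans 100/400, reference 250, factors 2.5/0.625
  # negatives scale to {5,10} in both samples: b = 7.5 + 2*sd = 7.5 + sqrt(50)
  # endogenous: 50*2.5 = 200*0.625 = 125; minus background; content factor 1
  expected_endo <- 125 - 7.5 - sqrt(50)
  expected_hk <- 50 - 7.5 - sqrt(50)
  expect_equal(unname(nx$norm_log2["E1", ]), rep(expected_endo, 2),
               tolerance = 1e-12)
  expect_equal(unname(nx$norm_log2["H1", ]), rep(expected_hk, 2),
               tolerance = 1e-12)
  nx2 <- normalize_counts(ex, norm_params())
  expect_equal(unname(nx2$norm_log2["E1", ]), rep(log2(110), 2))
})

test_that("identical samples normalize to log2 of the background-subtracted counts", {
  counts <- cbind(s1 = c(500, 300, 120, 30, 3, 5), s2 = c(500, 300, 120, 30, 3, 5),
                  s3 = c(500, 300, 120, 30, 3, 5))
  genes <- data.frame(gene = paste0("g", 1:6),
                      probe_class = c("Endogenous", "Endogenous", "Housekeeping",
                                      "Positive", "Negative", "Negative"),
                      panel = "p", stringsAsFactors = FALSE)
  samples <- data.frame(sample_id = colnames(counts), patient_id = colnames(counts),
                        timepoint = "pre", responder = c(TRUE, FALSE, TRUE),
                        stringsAsFactors = FALSE)
  nx <- normalize_counts(expression_experiment(counts, genes, samples))
  b <- mean(c(3, 5)) + 2 * sd(c(3, 5))
  expect_equal(unname(nx$norm_log2[1, ]),
               rep(log2(max(round_half_up(500 - b), 1)), 3))
  expect_equal(unname(nx$norm_log2[2, ]),
               rep(log2(max(round_half_up(300 - b), 1)), 3))
})

test_that("per-sample rescaling is inverted exactly up to the lane reference", {
  ex <- make_toy_exp()
  base <- normalize_counts(ex, norm_params(round_values = FALSE, take_log = FALSE))
  scaled <- ex$counts
  scaled[, 2] <- scaled[, 2] * 3
  n2 <- normalize_counts(expression_experiment(scaled, ex$genes, ex$samples),
                         norm_params(round_values = FALSE, take_log = FALSE))
  ratios <- n2$norm_log2 / base$norm_log2
  expect_lt(diff(range(ratios)), 1e-12)   # a single common factor
  # scale factors preserving the positive-control reference mean: exact identity
  scaled2 <- ex$counts
  scaled2[, 1] <- scaled2[, 1] * 2      # geomean 100 -> 200
  scaled2[, 2] <- scaled2[, 2] * 0.75   # geomean 400 -> 300; mean stays 250
  n3 <- normalize_counts(expression_experiment(scaled2, ex$genes, ex$samples),
                         norm_params(round_values = FALSE, take_log = FALSE))
  expect_equal(n3$norm_log2, base$norm_log2, tolerance = 1e-12)
})

test_that("moderated t matches the shrinkage-formula oracle and its d0 = 0 limit", {
  ex <- make_null_exp(71, n_genes = 5, n_samp = 6)
  mat <- ex$norm_log2[ex$genes$probe_class == "Endogenous", ]
  labels <- ex$samples$responder
  res <- moderated_t_group(ex, "responder")
  oracle <- moderated_t_oracle(mat, labels)
  expect_equal(res$t, unname(oracle$t), tolerance = 1e-8)
  # d0 -> 0 limit: ordinary two-sample (pooled-variance) t
  res0 <- moderated_t_group(ex, "responder", prior_df = 0)
  tt <- apply(mat, 1, function(v)
    t.test(v[labels], v[!labels], var.equal = TRUE)$statistic)
  expect_equal(res0$t, unname(tt), tolerance = 1e-8)
})

test_that("with many equal-variance genes the posterior variance pools", {
  set.seed(99)
  n_samp <- 12
  mat <- matrix(rnorm(2000 * n_samp, sd = 2), 2000)
  labels <- rep(c(TRUE, FALSE), each = n_samp / 2)
  oracle <- moderated_t_oracle(mat, labels)
  # common true variance 4: shrinkage target approaches it
  expect_lt(abs(oracle$s0_2 - 4), 0.5)
  expect_gt(oracle$d0, n_samp)  # strong shrinkage when variances are exchangeable
})

test_that("zero-variance genes are flagged with t = 0", {
  ex <- make_null_exp(72, n_genes = 6, n_samp = 8)
  ex$norm_log2[1, ] <- 5
  res <- moderated_t_group(ex, "responder")
  expect_true(res$zero_variance[1])
  expect_equal(res$t[1], 0)
  expect_equal(res$p[1], 1)
})

test_that("paired mixed model recovers closed forms in degenerate designs", {
  # perfectly paired: estimate equals the mean within-patient difference
  set.seed(5)
  n <- 7
  pre <- rnorm(n, 6, 1)
  diffs <- rnorm(n, -0.8, 0.3)
  counts <- matrix(1L, 4, 2 * n)  # placeholder raw counts
  genes <- data.frame(gene = c("G", "H", "P", "N"),
                      probe_class = c("Endogenous", "Housekeeping", "Positive",
                                      "Negative"),
                      panel = "p", stringsAsFactors = FALSE)
  samples <- data.frame(
    sample_id = paste0("s", 1:(2 * n)),
    patient_id = rep(paste0("pt", 1:n), 2),
    timepoint = rep(c("pre", "progression"), each = n),
    responder = TRUE, stringsAsFactors = FALSE)
  ex <- expression_experiment(counts, genes, samples)
  ex$norm_log2 <- rbind(G = c(pre, pre + diffs), H = 0, P = 0, N = 0)
  colnames(ex$norm_log2) <- samples$sample_id
  res <- paired_timepoint_lme(ex, genes = "G")
  expect_equal(res$estimate, mean(diffs), tolerance = 1e-6)
  # single timepoint only errors
  ex_pre <- subset_experiment(ex, samples$timepoint == "pre")
  expect_error(paired_timepoint_lme(ex_pre, genes = "G"), "pre and progression")
})

test_that("per-gene Cox matches a grid-search partial-likelihood oracle", {
  set.seed(14)
  n <- 8
  time <- sort(sample(10:100, n))
  event <- c(1, 1, 0, 1, 1, 0, 1, 1)
  ex <- make_null_exp(73, n_genes = 4, n_samp = n)
  res <- cox_per_gene(ex, time, event)
  for (g in seq_len(4)) {
    x <- ex$norm_log2[g, ]
    expect_lt(abs(res$log_hr[g] - cox_oracle(time, event, x)), 1e-6)
  }
  # two identical groups: log HR 0
  xx <- rep(c(0, 1), 4)
  tm <- rep(c(10, 20, 30, 40), each = 2)
  ev <- rep(1, 8)
  ex2 <- make_null_exp(74, n_genes = 1, n_samp = 8)
  ex2$norm_log2[ex2$genes$probe_class == "Endogenous", ] <- xx
  r2 <- cox_per_gene(ex2, tm, ev)
  expect_equal(r2$log_hr[1], 0, tolerance = 1e-8)
})

test_that("random covariates give uniform Cox p-values", {
  set.seed(15)
  nrep <- 300
  pv <- vapply(seq_len(nrep), function(i) {
    n <- 40
    time <- rexp(n, 0.02)
    event <- runif(n) < 0.8
    x <- rnorm(n)
    co <- summary(survival::coxph(survival::Surv(time, event) ~ x))$coefficients
    co[1, "Pr(>|z|)"]
  }, 0)
  expect_gt(mean(pv < 0.05), 0.02)
  expect_lt(mean(pv < 0.05), 0.09)
})

test_that("gene-set filtering applies the overlap and coverage rules", {
  ex <- make_null_exp(75, n_genes = 30, n_samp = 6)
  ex$norm_log2[ex$genes$gene %in% sprintf("g%03d", 26:30), ] <- 1  # constant
  panel_nc <- sprintf("g%03d", 1:25)
  sets <- list(
    ten_five = c(panel_nc[1:5], paste0("off", 1:5)),       # 5 >= 5, 0.5 >= 0.5
    twelve_five = c(panel_nc[6:10], paste0("off", 1:7)),   # coverage 0.417
    four_four = panel_nc[11:14],                           # overlap 4 < 5
    constant_six = c(panel_nc[15:18], sprintf("g%03d", 27:28))  # 4 non-constant
  )
  kept <- filter_gene_sets(sets, ex)
  expect_setequal(names(kept), "ten_five")
})

test_that("the global statistic matches its worked values and invariances", {
  expect_equal(global_stat(2), 2)
  expect_equal(global_stat(c(3, 4)), 5)
  set.seed(16)
  t <- rnorm(10)
  expect_equal(global_stat(t), global_stat(rev(t)))
  expect_equal(global_stat(t), global_stat(-t))
})

test_that("permutation tests are deterministic by seed with bounded p-values", {
  ex <- make_null_exp(76, n_genes = 40, n_samp = 12)
  sets <- list(a = sprintf("g%03d", 1:8), b = sprintf("g%03d", 9:20))
  r1 <- gene_set_tests(ex, "responder", sets, B = 99, seed = 5)
  r2 <- gene_set_tests(ex, "responder", sets, B = 99, seed = 5)
  expect_identical(r1, r2)
  expect_true(all(r1$perm_p >= 1 / 100 & r1$perm_p <= 1))
  expect_true(all(r1$fisher_perm_p >= 1 / 100 & r1$fisher_perm_p <= 1))
})

test_that("few distinct label assignments trigger exact enumeration", {
  ex <- make_null_exp(77, n_genes = 15, n_samp = 5)
  ex$samples$responder <- c(TRUE, TRUE, FALSE, FALSE, FALSE)  # choose(5,2) = 10
  sets <- list(a = sprintf("g%03d", 1:6))
  r1 <- gene_set_tests(ex, "responder", sets, B = 999, seed = 1, fisher = FALSE)
  r2 <- gene_set_tests(ex, "responder", sets, B = 999, seed = 2, fisher = FALSE)
  expect_identical(r1$perm_p, r2$perm_p)      # enumeration ignores the draws
  expect_true(r1$perm_p %in% (1:10 / 10))
})

test_that("competitive Fisher odds ratios follow the cross-tabulation rules", {
  # a=4, b=6, c=10, d=180 -> OR 12
  tb <- matrix(c(4, 6, 10, 180), 2, 2, byrow = TRUE)
  expect_equal((tb[1, 1] * tb[2, 2]) / (tb[1, 2] * tb[2, 1]), 12)
  sig <- c(rep(TRUE, 4), rep(FALSE, 6), rep(TRUE, 10), rep(FALSE, 180))
  or_pkg <- tcrbm:::haldane_or(tcrbm:::fisher_table(sig, 1:10))
  expect_equal(or_pkg, 12)
  # correction engages only when a cell is zero, keeping the OR finite
  sig2 <- c(rep(TRUE, 5), rep(FALSE, 20))
  or0 <- tcrbm:::haldane_or(tcrbm:::fisher_table(sig2, 1:5))
  expect_true(is.finite(or0) && or0 > 1)
})

test_that("membership independent of significance gives odds ratios near one", {
  set.seed(18)
  ors <- vapply(1:40, function(i) {
    sig <- runif(400) < 0.3
    tcrbm:::haldane_or(tcrbm:::fisher_table(sig, sample(400, 100)))
  }, 0)
  expect_lt(abs(mean(log(ors))), 0.15)
})

test_that("a configured IFN-set elevation is detected by the permutation test", {
  hits <- vapply(1:10, function(s) {
    cfg <- sim_config(n_patients = 24, seed = 800 + s,
                      expression_params = list(ifn_shift = 1.5, n_pre = 14,
                                               n_progression = 2, n_paired = 1))
    tr <- simulate_trial(cfg)
    ex <- normalize_counts(tr$expression)
    pre <- subset_experiment(ex, ex$samples$timepoint == "pre")
    if (sum(pre$samples$responder) < 2 || sum(!pre$samples$responder) < 2)
      return(NA)
    kept <- filter_gene_sets(tr$genesets["IFN_downstream"], pre)
    if (!length(kept)) return(FALSE)
    gs <- gene_set_tests(pre, group = "responder", sets = kept, B = 200,
                         seed = s, fisher = FALSE)
    gs$perm_p < 0.05
  }, TRUE)
  expect_gte(mean(hits, na.rm = TRUE), 0.8)
})
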