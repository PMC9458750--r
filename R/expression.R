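#' Construct an expression experiment
#'
#' Probe-class-annotated count container for nCounter-style data: a
#' gene x sample matrix of non-negative integer raw counts, probe annotations
#' (class in Endogenous/Housekeeping/Positive/Negative, panel), and sample
#' annotations (patient, timepoint pre/progression, responder). The
#' normalized log2 matrix is absent until [normalize_counts()] is applied.
#'
#' @param counts gene x sample matrix of non-negative integers.
#' @param genes data.frame with `gene`, `probe_class`, `panel`.
#' @param samples data.frame with `sample_id`, `patient_id`, `timepoint`,
#'   `responder`.
#' @return object of class `expression_experiment`.
#' @export
expression_experiment <- function(counts, genes, samples) {
  stopifnot(nrow(counts) == nrow(genes), ncol(counts) == nrow(samples))
  if (any(counts < 0) || any(counts != round(counts)))
    stop("raw counts must be non-negative integers", call. = FALSE)
  stopifnot(all(genes$probe_class %in%
                  c("Endogenous", "Housekeeping", "Positive", "Negative")))
  rownames(counts) <- genes$gene
  colnames(counts) <- samples$sample_id
  structure(list(counts = counts, genes = genes, samples = samples,
                 norm_log2 = NULL, norm_meta = NULL),
            class = "expression_experiment")
}

#' @method print expression_experiment
#' @export
print.expression_experiment <- function(x, ...) {
  cat(sprintf("expression_experiment: %d probes x %d samples (%s)\n",
              nrow(x$counts), ncol(x$counts),
              if (is.null(x$norm_log2)) "raw" else "normalized"))
  print(table(x$genes$probe_class))
  invisible(x)
}

#' Normalization parameter set
#'
#' The fixed nCounter normalization recipe: positive-control geometric-mean
#' lane scaling (CodeCount `geo.mean`), background subtraction at mean + 2 SD
#' of the negative controls (`mean.2sd`), housekeeping geometric-mean content
#' normalization (`housekeeping.geo.mean`), rounding, and log2. The three
#' method strings are fixed; alternatives are rejected. `round_values` and
#' `take_log` may be disabled to inspect intermediate values.
#'
#' @param code_count,background,sample_content method names (fixed).
#' @param round_values round to nearest integer, half away from zero.
#' @param take_log floor at 1 then log2.
#' @return list of class `norm_params`.
#' @export
norm_params <- function(code_count = "geo.mean", background = "mean.2sd",
                        sample_content = "housekeeping.geo.mean",
                        round_values = TRUE, take_log = TRUE) {
  if (!identical(code_count, "geo.mean"))
    stop("unsupported CodeCount method: ", code_count, call. = FALSE)
  if (!identical(background, "mean.2sd"))
    stop("unsupported Background method: ", background, call. = FALSE)
  if (!identical(sample_content, "housekeeping.geo.mean"))
    stop("unsupported SampleContent method: ", sample_content, call. = FALSE)
  structure(list(code_count = code_count, background = background,
                 sample_content = sample_content,
                 round_values = isTRUE(round_values),
                 take_log = isTRUE(take_log)),
            class = "norm_params")
}

#' Normalize nCounter-style counts
#'
#' Applies, separately within each panel, the four normalization steps in
#' order: (1) CodeCount lane scaling — per-sample positive-control geometric
#' mean g_s, factor f_s = mean_s(g_s) / g_s applied to all counts; (2)
#' Background — per-sample mean + 2 SD (sample SD, n-1) of the scaled
#' negative controls subtracted from Endogenous and Housekeeping counts,
#' floored at 0; (3) SampleContent — per-sample housekeeping geometric mean
#' h_s (post steps 1-2), factor mean_s(h_s) / h_s applied to Endogenous
#' counts; (4) rounding to the nearest integer (half away from zero) and
#' log2 after flooring values below 1 to 1. The reference level for steps 1
#' and 3 is the arithmetic mean across samples of the per-sample geometric
#' means; because that reference moves with the data, rescaling one sample is
#' undone exactly up to a single factor shared by the whole matrix.
#'
#' @param exp an [expression_experiment()].
#' @param params a [norm_params()].
#' @return the experiment with `norm_log2` (all probes; control probes carry
#'   the steps that apply to their class) and `norm_meta` describing the
#'   dialect.
#' @export
normalize_counts <- function(exp, params = norm_params()) {
  stopifnot(inherits(exp, "expression_experiment"))
  if (!inherits(params, "norm_params")) stop("params must be norm_params()", call. = FALSE)
  if (ncol(exp$counts) < 2) stop("normalization requires >= 2 samples", call. = FALSE)
  out <- matrix(NA_real_, nrow(exp$counts), ncol(exp$counts),
                dimnames = dimnames(exp$counts))
  for (pan in unique(exp$genes$panel)) {
    gsel <- exp$genes$panel == pan
    cls <- exp$genes$probe_class[gsel]
    m <- exp$counts[gsel, , drop = FALSE]
    for (cc in c("Positive", "Negative", "Housekeeping")) {
      if (!any(cls == cc))
        stop(sprintf("panel '%s' lacks %s control probes; cannot normalize",
                     pan, cc), call. = FALSE)
    }
    # (1) CodeCount
    g <- apply(m[cls == "Positive", , drop = FALSE], 2, geo_mean)
    if (any(g == 0))
      stop("zero positive-control geometric mean in sample ",
           colnames(m)[which(g == 0)[1]], call. = FALSE)
    m <- sweep(m, 2, mean(g) / g, `*`)
    # (2) Background
    negm <- m[cls == "Negative", , drop = FALSE]
    b <- apply(negm, 2, function(x) mean(x) + 2 * stats::sd(x))
    subj_rows <- cls %in% c("Endogenous", "Housekeeping")
    m[subj_rows, ] <- pmax(sweep(m[subj_rows, , drop = FALSE], 2, b, `-`), 0)
    # (3) SampleContent
    h <- apply(m[cls == "Housekeeping", , drop = FALSE], 2, geo_mean)
    if (any(h == 0))
      stop("zero housekeeping geometric mean in sample ",
           colnames(m)[which(h == 0)[1]], call. = FALSE)
    m[cls == "Endogenous", ] <- sweep(m[cls == "Endogenous", , drop = FALSE],
                                      2, mean(h) / h, `*`)
    # (4) round, (5) log2
    if (params$round_values) m <- round_half_up(m)
    if (params$take_log) m <- log2(pmax(m, 1))
    out[gsel, ] <- m
  }
  exp$norm_log2 <- out
  exp$norm_meta <- list(
    params = unclass(params),
    reference = "arithmetic mean across samples of per-sample geometric means",
    log_zero_handling = "values < 1 floored to 1 before log2",
    note = "background subtraction applied to Endogenous and Housekeeping; content factor applied to Endogenous only; panels normalized separately"
  )
  exp
}

endogenous_matrix <- function(exp) {
  if (is.null(exp$norm_log2)) stop("experiment is not normalized", call. = FALSE)
  exp$norm_log2[exp$genes$probe_class == "Endogenous", , drop = FALSE]
}

# moderated t on a matrix given binary labels; optionally with fixed prior
mod_t_matrix <- function(mat, labels, prior_df = NULL, prior_var = NULL) {
  g <- as.numeric(labels)
  design <- cbind(Intercept = 1, group = g)
  fit <- limma::lmFit(mat, design)
  sg2 <- fit$sigma^2
  dg <- fit$df.residual
  if (is.null(prior_df)) {
    # genes constant across samples are flagged below with t = 0; limma's
    # zero-variance offset warning adds nothing here
    sq <- suppressWarnings(limma::squeezeVar(sg2, dg))
    d0 <- sq$df.prior
    var_post <- sq$var.post
  } else {
    d0 <- prior_df
    var_post <- if (d0 == 0) sg2 else
      (d0 * (prior_var %||% mean(sg2)) + dg * sg2) / (d0 + dg)
  }
  coef <- fit$coefficients[, "group"]
  tstat <- coef / (fit$stdev.unscaled[, "group"] * sqrt(var_post))
  dft <- dg + d0
  flat <- apply(mat, 1, stats::sd) == 0
  tstat[flat] <- 0
  p <- 2 * stats::pt(-abs(tstat), dft)
  p[flat] <- 1
  data.frame(gene = rownames(mat), logFC = coef, t = tstat, p = p,
             df_total = dft, zero_variance = flat,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Moderated-t group comparison per gene
#'
#' Per-gene linear model of normalized log2 expression on a two-level
#' grouping (e.g. responder status), with empirical-Bayes variance
#' shrinkage: the posterior variance is (d0 s0^2 + dg sg^2) / (d0 + dg), the
#' prior (d0, s0^2) estimated by limma's moment matching on log sample
#' variances, and the moderated t referred to d0 + dg df. Genes constant
#' across all samples are flagged with t = 0.
#'
#' @param exp a normalized [expression_experiment()].
#' @param group logical/two-level vector over samples, or the name of a
#'   logical sample annotation column (default `"responder"`).
#' @param prior_df,prior_var optional fixed prior df/variance overriding the
#'   empirical-Bayes estimate (prior_df = 0 gives the ordinary t).
#' @return data.frame: gene, logFC, t, p, df_total, zero_variance.
#' @export
moderated_t_group <- function(exp, group = "responder",
                              prior_df = NULL, prior_var = NULL) {
  mat <- endogenous_matrix(exp)
  if (is.character(group) && length(group) == 1)
    group <- exp$samples[[group]]
  labels <- as.logical(group)
  if (sum(labels) < 2 || sum(!labels) < 2)
    stop("need >= 2 samples per group", call. = FALSE)
  mod_t_matrix(mat, labels, prior_df, prior_var)
}

#' Paired pre vs progression mixed-model comparison
#'
#' Per-gene (or set-averaged) linear mixed model of normalized log2
#' expression on timepoint with a random patient intercept, reusing the
#' censored-LME machinery with censoring disabled; Wald test with
#' small-sample df. The estimate is the progression-minus-pre log2 change.
#'
#' @param exp a normalized [expression_experiment()].
#' @param genes genes to fit (default: all endogenous).
#' @param set optional gene set (character vector); with
#'   `set_average = TRUE` the set-average expression per sample is fit as a
#'   single target.
#' @param set_average average over the set before fitting.
#' @return data.frame: target, estimate, se, df, p.
#' @export
paired_timepoint_lme <- function(exp, genes = NULL, set = NULL,
                                 set_average = FALSE) {
  mat <- endogenous_matrix(exp)
  smp <- exp$samples
  if (length(unique(smp$timepoint)) < 2)
    stop("need both pre and progression samples", call. = FALSE)
  targets <- if (set_average) {
    stopifnot(!is.null(set))
    gsel <- intersect(set, rownames(mat))
    list(set_average = colMeans(mat[gsel, , drop = FALSE]))
  } else {
    gs <- genes %||% (if (!is.null(set)) intersect(set, rownames(mat)) else rownames(mat))
    stats::setNames(lapply(gs, function(g) mat[g, ]), gs)
  }
  rows <- lapply(names(targets), function(nm) {
    d <- data.frame(value = targets[[nm]],
                    patient_id = smp$patient_id,
                    timepoint = factor(smp$timepoint,
                                       levels = c("pre", "progression")))
    fit <- fit_censored_lme(d, fixed = ~ timepoint, subject = "patient_id",
                            value = "value", censored = ".none",
                            log_transform = FALSE)
    L <- c(0, 1)
    w <- contrast_wald(fit, L, label = nm)
    data.frame(target = nm, estimate = w$log_ratio, se = w$se, df = w$df,
               p = w$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  row.names(out) <- NULL
  out
}

#' Per-gene Cox proportional-hazards PFS models
#'
#' Single-covariate Cox fits (Efron ties) of survival on normalized log2
#' expression, one gene at a time. Monotone-likelihood fits (separation) are
#' flagged and their estimate capped at +/- 15.
#'
#' @param exp a normalized [expression_experiment()].
#' @param time,event survival time and event indicator aligned with the
#'   experiment's samples.
#' @return data.frame: gene, log_hr, se, p, flagged.
#' @export
cox_per_gene <- function(exp, time, event) {
  mat <- endogenous_matrix(exp)
  stopifnot(length(time) == ncol(mat), length(event) == ncol(mat))
  if (sum(event) < 1) stop("need >= 1 event", call. = FALSE)
  rows <- lapply(rownames(mat), function(g) {
    x <- mat[g, ]
    flagged <- FALSE
    fit <- withCallingHandlers(
      survival::coxph(survival::Surv(time, event) ~ x, ties = "efron"),
      warning = function(w) {
        flagged <<- TRUE
        invokeRestart("muffleWarning")
      })
    co <- summary(fit)$coefficients
    est <- co[1, "coef"]
    if (!is.finite(est) || abs(est) > 15) {
      flagged <- TRUE
      est <- sign(est) * 15
    }
    data.frame(gene = g, log_hr = est, se = co[1, "se(coef)"],
               p = co[1, "Pr(>|z|)"], flagged = flagged,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  row.names(out) <- NULL
  out
}

#' Filter gene sets for panel coverage
#'
#' A set is retained iff it has at least `min_overlap` overlapping
#' non-constant genes on the panel AND that overlap covers at least
#' `min_coverage` of the original set. Non-constant means nonzero variance
#' of normalized log2 expression across samples.
#'
#' @param collection named list of gene-symbol vectors.
#' @param exp a normalized [expression_experiment()] providing the panel and
#'   expression matrix.
#' @param min_overlap,min_coverage filter thresholds (study values 5, 0.5).
#' @return the retained sub-collection, with an `overlap` attribute.
#' @export
filter_gene_sets <- function(collection, exp, min_overlap = 5,
                             min_coverage = 0.5) {
  mat <- endogenous_matrix(exp)
  nonconstant <- rownames(mat)[apply(mat, 1, stats::sd) > 0]
  ok <- vapply(collection, function(genes) {
    ov <- length(intersect(genes, nonconstant))
    ov >= min_overlap && ov / length(genes) >= min_coverage
  }, TRUE)
  out <- collection[ok]
  attr(out, "overlap") <- vapply(out, function(genes)
    length(intersect(genes, nonconstant)), 0L)
  out
}

#' Gene-set global significance statistic
#'
#' The set summary of differential expression: sqrt of the sum of squared
#' per-gene t-statistics.
#'
#' @param tstats numeric vector of t-statistics for the set's genes.
#' @return non-negative statistic.
#' @export
global_stat <- function(tstats) sqrt(sum(tstats^2))

# label permutations shared by both permutation tests; exact enumeration when
# fewer than `exact_below` distinct assignments exist
permutation_labels <- function(labels, B, exact_below = 20) {
  n <- length(labels)
  n1 <- sum(labels)
  n_distinct <- choose(n, n1)
  if (n_distinct < exact_below) {
    combos <- utils::combn(n, n1)
    perms <- lapply(seq_len(ncol(combos)), function(j) {
      l <- rep(FALSE, n); l[combos[, j]] <- TRUE; l
    })
    list(perms = perms, exact = TRUE)
  } else {
    list(perms = lapply(seq_len(B), function(i) sample(labels)), exact = FALSE)
  }
}

#' Permutation gene-set tests
#'
#' For each set, computes (a) the global significance statistic
#' sqrt(sum t^2) over the set's genes with a permutation p-value obtained by
#' permuting sample group labels and recomputing the per-gene moderated t;
#' and (b) the competitive Fisher test: the 2x2 cross-tabulation of set
#' membership against nominal significance (p < alpha), with odds ratio
#' ad/(bc) (Haldane 0.5 correction only when a cell is 0) and a permutation
#' p-value using the Fisher exact-test p as objective. Permutation p-values
#' use the add-one estimator (1 + #{perm at least as extreme}) / (B + 1);
#' when fewer than 20 distinct label assignments exist, all are enumerated
#' and the p-value is the exact proportion.
#'
#' @param exp a normalized [expression_experiment()].
#' @param group logical sample grouping (or annotation column name).
#' @param sets named list of gene sets (typically pre-filtered with
#'   [filter_gene_sets()]).
#' @param B number of permutations (study default 5000).
#' @param seed integer seed for the permutations.
#' @param alpha nominal significance threshold for the Fisher table.
#' @return data.frame: set, n_overlap, global_stat, perm_p, fisher_or,
#'   fisher_p, fisher_perm_p.
#' @export
gene_set_tests <- function(exp, group = "responder", sets, B = 5000,
                           seed = 1L, alpha = 0.05, fisher = TRUE) {
  mat <- endogenous_matrix(exp)
  if (is.character(group) && length(group) == 1)
    group <- exp$samples[[group]]
  labels <- as.logical(group)
  set.seed(seed)
  obs <- mod_t_matrix(mat, labels)
  sets_idx <- lapply(sets, function(g) which(obs$gene %in% g))
  obs_stat <- vapply(sets_idx, function(i) global_stat(obs$t[i]), 0)
  if (fisher) {
    obs_sig <- obs$p < alpha
    obs_tab <- lapply(sets_idx, function(i) fisher_table(obs_sig, i))
    obs_or <- vapply(obs_tab, haldane_or, 0)
    obs_fp <- vapply(obs_tab, function(tb) stats::fisher.test(tb)$p.value, 0)
  }

  pl <- permutation_labels(labels, B)
  nperm <- length(pl$perms)
  ge_stat <- numeric(length(sets))
  le_fp <- numeric(length(sets))
  for (k in seq_len(nperm)) {
    pt_ <- mod_t_matrix(mat, pl$perms[[k]])
    if (fisher) sig <- pt_$p < alpha
    for (j in seq_along(sets_idx)) {
      i <- sets_idx[[j]]
      if (global_stat(pt_$t[i]) >= obs_stat[j]) ge_stat[j] <- ge_stat[j] + 1
      if (fisher &&
          stats::fisher.test(fisher_table(sig, i))$p.value <= obs_fp[j])
        le_fp[j] <- le_fp[j] + 1
    }
  }
  if (pl$exact) {
    perm_p <- ge_stat / nperm
    fisher_perm_p <- le_fp / nperm
  } else {
    perm_p <- (1 + ge_stat) / (nperm + 1)
    fisher_perm_p <- (1 + le_fp) / (nperm + 1)
  }
  out <- data.frame(
    set = names(sets),
    n_overlap = lengths(sets_idx),
    global_stat = obs_stat,
    perm_p = perm_p,
    stringsAsFactors = FALSE, row.names = NULL
  )
  if (fisher) {
    out$fisher_or <- obs_or
    out$fisher_p <- obs_fp
    out$fisher_perm_p <- fisher_perm_p
  }
  out
}

fisher_table <- function(sig, set_idx) {
  inset <- seq_along(sig) %in% set_idx
  matrix(c(sum(inset & sig), sum(inset & !sig),
           sum(!inset & sig), sum(!inset & !sig)),
         2, 2, byrow = TRUE)
}

haldane_or <- function(tb) {
  if (any(tb == 0)) tb <- tb + 0.5
  (tb[1, 1] * tb[2, 2]) / (tb[1, 2] * tb[2, 1])
}

#' @rdname gene_set_tests
#' @export
global_significance <- function(exp, group = "responder", sets, B = 5000,
                                seed = 1L) {
  gene_set_tests(exp, group, sets, B, seed, fisher = FALSE)
}

#' @rdname gene_set_tests
#' @export
competitive_fisher <- function(exp, group = "responder", sets, B = 5000,
                               seed = 1L, alpha = 0.05) {
  gene_set_tests(exp, group, sets, B, seed, alpha)[, c("set", "n_overlap",
                                                       "fisher_or", "fisher_p",
                                                       "fisher_perm_p")]
}
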