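#' Exact Clopper-Pearson binomial confidence interval
#'
#' Exact tail-inversion bounds for a response proportion: the lower bound
#' solves P(X >= k | p) = (1-level)/2 (0 when k = 0) and the upper bound
#' solves P(X <= k | p) = (1-level)/2 (1 when k = n), X ~ Binomial(n, p),
#' computed through the beta-quantile closed form. Display values use
#' half-away-from-zero rounding to 2 decimals, which reproduces the printed
#' efficacy-table bounds.
#'
#' @param k number of responders (0 <= k <= n).
#' @param n number of patients (>= 1).
#' @param level confidence level (default 0.95).
#' @return list: k, n, orr, ci_low, ci_high (exact), ci_low_2dp, ci_high_2dp
#'   (display-rounded).
#' @export
clopper_pearson <- function(k, n, level = 0.95) {
  if (length(k) != 1 || length(n) != 1 || is.na(k) || is.na(n) ||
      n < 1 || k < 0 || k > n || k != round(k) || n != round(n))
    stop("require integers 0 <= k <= n, n >= 1", call. = FALSE)
  a <- (1 - level) / 2
  lo <- if (k == 0) 0 else stats::qbeta(a, k, n - k + 1)
  hi <- if (k == n) 1 else stats::qbeta(1 - a, k + 1, n - k)
  list(k = k, n = n, orr = k / n, ci_low = lo, ci_high = hi,
       ci_low_2dp = round_half_up(lo, 2), ci_high_2dp = round_half_up(hi, 2))
}

#' Wilcoxon rank-sum test
#'
#' Two-sided rank-sum comparison with the exact null enumeration when the
#' pooled size is at most 20 and there are no ties, and the normal
#' approximation with tie and continuity corrections otherwise. Missing
#' values are dropped.
#'
#' @param x,y numeric vectors (each >= 1 non-missing value).
#' @return list: W (rank-sum statistic for `x` on the Mann-Whitney scale),
#'   p, exact flag.
#' @export
wilcoxon_rank_sum <- function(x, y) {
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  if (!length(x) || !length(y)) stop("empty group after dropping NA", call. = FALSE)
  ties <- anyDuplicated(c(x, y)) > 0
  use_exact <- (length(x) + length(y) <= 20) && !ties
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = use_exact,
                                            correct = TRUE))
  list(W = unname(wt$statistic), p = wt$p.value, exact = use_exact)
}

#' Spearman rank-correlation test
#'
#' Correlation of average ranks with the t-approximation p-value
#' t = rho sqrt((n-2) / (1-rho^2)) on n-2 df. Pairs with any missing value
#' are dropped.
#'
#' @param x,y numeric vectors (>= 3 complete pairs).
#' @return list: rho, p, n.
#' @export
spearman_test <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need >= 3 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("rho undefined for a constant vector", call. = FALSE)
  rho <- stats::cor(rank(x), rank(y))
  p <- if (abs(rho) >= 1) 0 else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(-abs(tstat), n - 2)
  }
  list(rho = rho, p = p, n = n)
}

# least-absolute-deviation fit: intercept-only closed form (sample median),
# otherwise epsilon-smoothed iteratively reweighted least squares
lad_fit <- function(y, X, eps = 1e-8, maxit = 200) {
  if (ncol(X) == 1 && all(X == 1)) return(stats::median(y))
  beta <- stats::lm.fit(X, y)$coefficients
  beta[is.na(beta)] <- 0
  for (it in seq_len(maxit)) {
    r <- y - drop(X %*% beta)
    w <- 1 / pmax(abs(r), eps)
    new <- tryCatch(stats::lm.wfit(X, y, w)$coefficients,
                    error = function(e) beta)
    new[is.na(new)] <- 0
    if (max(abs(new - beta)) < 1e-10 * max(1, max(abs(beta)))) {
      beta <- new
      break
    }
    beta <- new
  }
  beta
}

#' Bootstrapped median regression
#'
#' Least-absolute-deviation regression of `y` on a group indicator plus
#' optional adjustment covariates, with a two-sided bootstrap p-value for
#' the group coefficient: subjects are resampled with replacement, the LAD
#' fit repeated, and p = 2 min(frac(coef* <= 0), frac(coef* >= 0)) clipped
#' to [1/B, 1].
#'
#' @param y response.
#' @param group two-level grouping (coefficient reported for the second
#'   level vs the first).
#' @param covariates optional data.frame of adjustment covariates.
#' @param B bootstrap resamples (study value 10000).
#' @param seed integer seed.
#' @return list: coef (group effect), p, B.
#' @export
bootstrap_median_regression <- function(y, group, covariates = NULL,
                                        B = 10000, seed = 1L) {
  stopifnot(B >= 100)
  g <- factor(group)
  if (nlevels(g) != 2 || min(table(g)) < 2)
    stop("need a two-level group with >= 2 per level", call. = FALSE)
  df <- data.frame(g = g)
  if (!is.null(covariates)) df <- cbind(df, covariates)
  X <- stats::model.matrix(~ ., df)
  if (stats::sd(y) == 0) return(list(coef = 0, p = 1, B = B))
  j <- 2L  # group coefficient column (second level of g)
  coef_obs <- lad_fit(y, X)[j]
  set.seed(seed)
  n <- length(y)
  boots <- numeric(B)
  for (b in seq_len(B)) {
    idx <- sample.int(n, n, replace = TRUE)
    Xb <- X[idx, , drop = FALSE]
    boots[b] <- if (qr(Xb)$rank < ncol(Xb)) NA_real_ else lad_fit(y[idx], Xb)[j]
  }
  boots <- boots[!is.na(boots)]
  p <- 2 * min(mean(boots <= 0), mean(boots >= 0))
  list(coef = unname(coef_obs), p = min(1, max(p, 1 / B)), B = B)
}

#' Logistic association of response with a covariate
#'
#' Maximum-likelihood logistic regression of a binary response on a single
#' covariate with a Wald p-value; complete separation is flagged (no finite
#' MLE is claimed).
#'
#' @param response logical/0-1 vector (both classes present).
#' @param x covariate.
#' @return list: coef, se, p, separation flag.
#' @export
logistic_association <- function(response, x) {
  r <- as.logical(response)
  if (length(unique(r[!is.na(r)])) < 2)
    stop("both response classes must be present", call. = FALSE)
  sep <- FALSE
  fit <- withCallingHandlers(
    stats::glm(r ~ x, family = stats::binomial(),
               control = stats::glm.control(epsilon = 1e-10, maxit = 100)),
    warning = function(w) {
      sep <<- TRUE
      invokeRestart("muffleWarning")
    })
  co <- summary(fit)$coefficients
  if (!"x" %in% rownames(co) || is.na(stats::coef(fit)["x"])) {
    # degenerate covariate (constant): no association estimable
    return(list(coef = 0, se = NA_real_, p = 1, separation = FALSE))
  }
  eps <- 1e-8
  if (max(fit$fitted.values) > 1 - eps || min(fit$fitted.values) < eps)
    sep <- TRUE
  list(coef = co["x", "Estimate"], se = co["x", "Std. Error"],
       p = co["x", "Pr(>|z|)"], separation = sep)
}

#' Kaplan-Meier, log-rank and Cox summaries
#'
#' Product-limit survival summaries per group (median with Brookmeyer-Crowley
#' style confidence bounds read off the survfit confidence band), a
#' two-group log-rank test when `group` has two levels, and a
#' single-covariate Cox model (Efron ties) when `covariate` is supplied.
#'
#' @param time,event survival times and event indicators (>= 1 event).
#' @param group optional grouping factor.
#' @param covariate optional continuous covariate (e.g. log Cmax).
#' @param level confidence level for the KM median CI.
#' @return list with `km` (data.frame: group, n, events, median, ci_lo,
#'   ci_hi), `logrank_p` (or NA), and `cox` (list log_hr, se, p; or NULL).
#' @export
km_logrank_cox <- function(time, event, group = NULL, covariate = NULL,
                           level = 0.95) {
  if (sum(event) < 1)
    stop("no events: medians missing and tests undefined", call. = FALSE)
  grp <- if (is.null(group)) factor(rep("all", length(time))) else factor(group)
  sf <- if (is.null(group))
    survival::survfit(survival::Surv(time, event) ~ 1, conf.int = level)
  else
    survival::survfit(survival::Surv(time, event) ~ grp, conf.int = level)
  tab <- summary(sf)$table
  if (is.null(dim(tab))) tab <- matrix(tab, 1, dimnames = list("all", names(tab)))
  # median read-off: first time at which the survival estimate drops to <= 0.5
  # (with no censoring and even n this is the lower central order statistic);
  # CI bounds from the confidence band crossing 0.5 (survfit convention)
  strata_id <- if (is.null(sf$strata)) rep(1L, length(sf$time)) else
    rep(seq_along(sf$strata), sf$strata)
  med <- vapply(seq_len(nrow(tab)), function(i) {
    tt <- sf$time[strata_id == i]
    ss <- sf$surv[strata_id == i]
    if (!any(ss <= 0.5)) NA_real_ else min(tt[ss <= 0.5])
  }, 0)
  km <- data.frame(
    group = sub("^grp=", "", rownames(tab)),
    n = tab[, "records"],
    events = tab[, "events"],
    median = med,
    ci_lo = tab[, grep("LCL", colnames(tab))],
    ci_hi = tab[, grep("UCL", colnames(tab))],
    stringsAsFactors = FALSE, row.names = NULL
  )
  logrank_p <- NA_real_
  if (!is.null(group) && nlevels(grp) >= 2) {
    sd_ <- survival::survdiff(survival::Surv(time, event) ~ grp)
    logrank_p <- stats::pchisq(sd_$chisq, df = nlevels(grp) - 1,
                               lower.tail = FALSE)
  }
  cox <- NULL
  if (!is.null(covariate)) {
    cf <- survival::coxph(survival::Surv(time, event) ~ covariate,
                          ties = "efron")
    co <- summary(cf)$coefficients
    cox <- list(log_hr = co[1, "coef"], se = co[1, "se(coef)"],
                p = co[1, "Pr(>|z|)"])
  }
  list(km = km, logrank_p = logrank_p, cox = cox)
}

#' Cohort efficacy table
#'
#' Per-cohort overall response rate with exact Clopper-Pearson intervals
#' (display rounding: whole-percent ORR, 2-decimal bounds) and Kaplan-Meier
#' median PFS/OS with confidence bounds.
#'
#' @param patients patient table (cohort, responder/best_response, pfs/os
#'   columns).
#' @return data.frame, one row per cohort.
#' @export
efficacy_table <- function(patients) {
  rows <- lapply(sort(unique(patients$cohort)), function(ch) {
    p <- patients[patients$cohort == ch, ]
    k <- sum(p$best_response %in% c("CR", "PR"))
    cp <- clopper_pearson(k, nrow(p))
    pfs <- km_logrank_cox(p$pfs_days, p$pfs_event)$km
    os <- km_logrank_cox(p$os_days, p$os_event)$km
    data.frame(
      cohort = ch, n = nrow(p), responders = k,
      orr_pct = round_half_up(100 * cp$orr),
      orr_ci_low = cp$ci_low_2dp, orr_ci_high = cp$ci_high_2dp,
      pfs_median = pfs$median, pfs_ci_lo = pfs$ci_lo, pfs_ci_hi = pfs$ci_hi,
      os_median = os$median, os_ci_lo = os$ci_lo, os_ci_hi = os$ci_hi,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  row.names(out) <- NULL
  out
}
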