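# Left-censored linear mixed model with a single random subject intercept.
#
# The marginal likelihood integrates, per subject, the product of normal
# densities (observed log concentrations) and normal CDFs (values censored at
# the log LLOQ) over the random intercept. The integral is one-dimensional
# and is evaluated by adaptive Gauss-Hermite quadrature with per-subject
# centres and scales fixed from a pilot normal-LME fit (censored values
# treated as observed at the LLOQ), which keeps the approximated objective
# smooth so an analytic gradient can be used. When censoring is absent the
# integrand is Gaussian and the adapted rule is exact, so the censored
# likelihood coincides with the standard LME likelihood.

# ---- internal: data bundle ----

build_lme_inputs <- function(data, fixed, subject, value, lloq, censored,
                             log_transform) {
  stopifnot(is.data.frame(data))
  v <- data[[value]]
  cens <- if (censored %in% names(data)) as.logical(data[[censored]]) else
    rep(FALSE, nrow(data))
  cens[is.na(cens)] <- FALSE
  if (log_transform && any(v <= 0))
    stop("values must be positive for log transformation", call. = FALSE)
  y <- if (log_transform) log(v) else v
  X <- stats::model.matrix(fixed, data)
  subj <- factor(data[[subject]])
  list(y = y, X = X, cens = cens, subj = subj,
       xlevels = stats::.getXlevels(stats::terms(fixed), stats::model.frame(fixed, data)))
}

# adaptive quadrature geometry from pilot estimates (censored-as-observed)
gh_centers <- function(y, X, subj, beta, sigma_b, sigma_e) {
  res <- y - drop(X %*% beta)
  n_i <- tabulate(subj)
  sum_i <- rowsum(res, subj)[, 1]
  sb2 <- max(sigma_b, 1e-8)^2
  cshr <- sb2 / (sigma_e^2 + n_i * sb2)
  m <- cshr * sum_i
  s <- sqrt(sb2 * sigma_e^2 / (sigma_e^2 + n_i * sb2))
  s <- pmax(s, 1e-6 * sigma_e)
  list(m = m, s = s)
}

# log-likelihood and analytic gradient of (beta, log sigma_b, log sigma_e)
censored_lme_objective <- function(par, y, X, cens, subj, gh, centers) {
  p <- ncol(X)
  beta <- par[seq_len(p)]
  sb <- exp(par[p + 1])
  se <- exp(par[p + 2])
  S <- nlevels(subj)
  K <- length(gh$nodes)
  si <- as.integer(subj)
  B <- outer(centers$m, rep(1, K)) + sqrt(2) * centers$s %o% gh$nodes  # S x K
  lw <- log(sqrt(2) * centers$s) %o% rep(1, K) +
    matrix(log(gh$weights) + gh$nodes^2, S, K, byrow = TRUE)
  eta <- drop(X %*% beta)
  Rm <- matrix(y - eta, length(y), K) - B[si, , drop = FALSE]        # N x K
  Mrow <- matrix(0, length(y), K)
  if (any(!cens)) {
    Ro <- Rm[!cens, , drop = FALSE]
    Mrow[!cens, ] <- -0.5 * log(2 * pi * se^2) - Ro^2 / (2 * se^2)
  }
  lam <- NULL
  if (any(cens)) {
    U <- Rm[cens, , drop = FALSE] / se
    logPhi <- stats::pnorm(U, log.p = TRUE)
    Mrow[cens, ] <- logPhi
    lam <- exp(stats::dnorm(U, log = TRUE) - logPhi)
  }
  persub <- rowsum(Mrow, si, reorder = TRUE)                          # S x K
  logint <- persub + (-0.5 * log(2 * pi * sb^2) - B^2 / (2 * sb^2)) + lw
  Li <- logsumexp_rows(logint)
  ll <- sum(Li)
  P <- exp(logint - Li)                                               # S x K
  Prow <- P[si, , drop = FALSE]
  psi <- matrix(0, length(y), K)
  g_lse <- 0
  if (any(!cens)) {
    Ro <- Rm[!cens, , drop = FALSE]
    psi[!cens, ] <- Ro / se^2
    g_lse <- g_lse + sum(Prow[!cens, , drop = FALSE] * (Ro^2 / se^2 - 1))
  }
  if (any(cens)) {
    U <- Rm[cens, , drop = FALSE] / se
    psi[cens, ] <- -lam / se
    g_lse <- g_lse + sum(Prow[cens, , drop = FALSE] * (-U * lam))
  }
  q <- rowSums(Prow * psi)
  g_beta <- drop(crossprod(X, q))
  g_lsb <- sum(P * (B^2 / sb^2 - 1))
  list(ll = ll, grad = c(g_beta, g_lsb, g_lse))
}

#' Evaluate the censored marginal log-likelihood
#'
#' Computes the left-censored random-intercept marginal log-likelihood at the
#' supplied parameter values, using adaptive Gauss-Hermite quadrature centred
#' for those values. With no censored observations the adapted rule is exact,
#' so this equals the standard normal-LME log-likelihood.
#'
#' @param fit a `censored_lme` fit (supplies data and design).
#' @param beta,sigma_b,sigma_e parameter values (default: the fit's
#'   estimates).
#' @param gh_nodes number of quadrature nodes.
#' @return log-likelihood value.
#' @export
censored_lme_loglik <- function(fit, beta = fit$beta, sigma_b = fit$sigma_b,
                                sigma_e = fit$sigma_e, gh_nodes = 30) {
  gh <- gauss_hermite(gh_nodes)
  centers <- gh_centers(fit$y, fit$X, fit$subject, beta, sigma_b, sigma_e)
  censored_lme_objective(c(beta, log(max(sigma_b, 1e-8)), log(sigma_e)),
                         fit$y, fit$X, fit$cens, fit$subject, gh, centers)$ll
}

# ---- internal: normal-LME via lme4 (study rule for <= 1 censored value) ----

fit_lme4_path <- function(y, X, subj) {
  df <- data.frame(.y = y, .subj = subj)
  df$.X <- X
  # boundary (sigma_b = 0) fits are valid ML solutions, and lme4's gradient
  # check is overly strict for these balanced designs; keep both quiet
  fit <- suppressWarnings(suppressMessages(
    lme4::lmer(.y ~ 0 + .X + (1 | .subj), data = df, REML = FALSE)))
  vc <- lme4::VarCorr(fit)
  beta <- lme4::fixef(fit)
  names(beta) <- colnames(X)
  vb <- as.matrix(stats::vcov(fit))
  dimnames(vb) <- list(colnames(X), colnames(X))
  list(beta = beta, vcov = vb,
       sigma_b = sqrt(as.numeric(vc$.subj[1])),
       sigma_e = stats::sigma(fit),
       loglik = as.numeric(stats::logLik(fit)),
       converged = TRUE, method = "lme4_ml")
}

# ---- main fit ----

#' Fit a left-censored random-intercept linear mixed model
#'
#' Fits log concentration ~ fixed effects + random subject intercept by
#' maximum likelihood, with left-censoring at the LLOQ handled through the
#' marginal likelihood (normal density for observed values, normal CDF at the
#' log LLOQ for censored ones). Following the source analysis rule, analytes
#' with at most one censored value are fit as an exact normal LME
#' (`lme4::lmer`, ML); with two or more, the censored likelihood is maximized
#' by quasi-Newton (L-BFGS-B) on (beta, log sigma_b, log sigma_e) with an
#' analytic gradient, adaptive 30-node Gauss-Hermite quadrature, and three
#' deterministic starts.
#'
#' @param data data.frame in long format; censored rows must carry the LLOQ
#'   as their value.
#' @param fixed one-sided formula for the fixed effects, e.g.
#'   `~ responder * timepoint`.
#' @param subject name of the subject identifier column.
#' @param value,lloq,censored column names.
#' @param log_transform model on the natural-log scale (default TRUE).
#' @param gh_nodes quadrature nodes for the censored path.
#' @param random_intercept set FALSE to drop the random intercept (then an
#'   uncensored fit reduces to ordinary least squares).
#' @return object of class `censored_lme` with elements beta, vcov, sigma_b,
#'   sigma_e, loglik, n_censored, converged, method, and the design needed
#'   for [approximate_df()] and [wald_ratio_timecourse()].
#' @export
fit_censored_lme <- function(data, fixed = ~ responder * timepoint,
                             subject = "patient_id", value = "value",
                             lloq = "lloq", censored = "censored",
                             log_transform = TRUE, gh_nodes = 30,
                             random_intercept = TRUE) {
  inp <- build_lme_inputs(data, fixed, subject, value, lloq, censored,
                          log_transform)
  y <- inp$y; X <- inp$X; cens <- inp$cens; subj <- inp$subj
  if (all(cens)) stop("all observations are censored; model not identifiable",
                      call. = FALSE)
  n_censored <- sum(cens)
  p <- ncol(X)

  if (!random_intercept) {
    if (n_censored > 0)
      stop("random_intercept = FALSE is only supported without censoring",
           call. = FALSE)
    ols <- stats::lm.fit(X, y)
    rss <- sum(ols$residuals^2)
    s2 <- rss / length(y)
    fitobj <- list(beta = stats::setNames(ols$coefficients, colnames(X)),
                   vcov = chol2inv(chol(crossprod(X))) * rss / (length(y) - p),
                   sigma_b = 0, sigma_e = sqrt(s2),
                   loglik = -0.5 * length(y) * (log(2 * pi * s2) + 1),
                   converged = TRUE, method = "ols")
  } else if (n_censored <= 1) {
    fitobj <- fit_lme4_path(y, X, subj)
  } else {
    fitobj <- fit_gh_path(y, X, cens, subj, gh_nodes)
  }

  timepoint_uncensored <- if ("timepoint" %in% names(data))
    table(factor(data$timepoint)[!cens]) else NULL
  structure(c(fitobj, list(
    n_censored = n_censored, y = y, X = X, cens = cens, subject = subj,
    fixed = fixed, xlevels = inp$xlevels,
    timepoint_uncensored = timepoint_uncensored,
    n_obs = length(y), n_subjects = nlevels(subj)
  )), class = "censored_lme")
}

fit_gh_path <- function(y, X, cens, subj, gh_nodes) {
  p <- ncol(X)
  gh <- gauss_hermite(gh_nodes)
  # pilot: censored-as-observed normal LME
  pilot <- fit_lme4_path(y, X, subj)
  centers <- gh_centers(y, X, subj, pilot$beta, pilot$sigma_b, pilot$sigma_e)
  lsb0 <- log(max(pilot$sigma_b, 1e-3 * pilot$sigma_e))
  lse0 <- log(pilot$sigma_e)
  starts <- list(c(pilot$beta, lsb0, lse0),
                 c(pilot$beta, lsb0 + 0.5, lse0 - 0.3),
                 c(pilot$beta, lsb0 - 0.5, lse0 + 0.3))
  sdy <- stats::sd(y)
  lower <- c(rep(-Inf, p), log(1e-5 * sdy), log(1e-5 * sdy))
  upper <- c(rep(Inf, p), log(1e3 * sdy), log(1e3 * sdy))
  best <- NULL
  for (st in starts) {
    opt <- try(stats::optim(
      st,
      fn = function(par) -censored_lme_objective(par, y, X, cens, subj, gh, centers)$ll,
      gr = function(par) -censored_lme_objective(par, y, X, cens, subj, gh, centers)$grad,
      method = "L-BFGS-B", lower = lower, upper = upper,
      control = list(maxit = 500, factr = 1e4)), silent = TRUE)
    if (inherits(opt, "try-error")) next
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best)) stop("censored LME optimization failed", call. = FALSE)
  par <- best$par
  obj <- censored_lme_objective(par, y, X, cens, subj, gh, centers)
  gnorm <- sqrt(sum(obj$grad^2))
  converged <- best$convergence == 0 && gnorm < 1e-3 * max(1, abs(obj$ll))
  # observed information via central differences of the analytic gradient
  np <- length(par)
  H <- matrix(0, np, np)
  h <- pmax(1e-5, 1e-5 * abs(par))
  for (j in seq_len(np)) {
    pp <- par; pp[j] <- pp[j] + h[j]
    pm <- par; pm[j] <- pm[j] - h[j]
    gp <- censored_lme_objective(pp, y, X, cens, subj, gh, centers)$grad
    gm <- censored_lme_objective(pm, y, X, cens, subj, gh, centers)$grad
    H[, j] <- -(gp - gm) / (2 * h[j])
  }
  H <- (H + t(H)) / 2
  Vfull <- try(solve(H), silent = TRUE)
  if (inherits(Vfull, "try-error") || anyNA(Vfull)) {
    Vfull <- try(solve(H + diag(1e-8, np)), silent = TRUE)
    if (inherits(Vfull, "try-error")) {
      Vfull <- matrix(NA_real_, np, np)
      converged <- FALSE
    }
  }
  vb <- Vfull[seq_len(p), seq_len(p), drop = FALSE]
  dimnames(vb) <- list(colnames(X), colnames(X))
  list(beta = stats::setNames(par[seq_len(p)], colnames(X)), vcov = vb,
       sigma_b = exp(par[p + 1]), sigma_e = exp(par[p + 2]),
       loglik = obj$ll, converged = converged, method = "gh_ml",
       grad_norm = gnorm)
}

#' @method print censored_lme
#' @export
print.censored_lme <- function(x, ...) {
  cat(sprintf("Left-censored LME fit (%s): %d obs, %d subjects, %d censored\n",
              x$method, x$n_obs, x$n_subjects, x$n_censored))
  cat(sprintf("  sigma_b = %.4f, sigma_e = %.4f, logLik = %.3f, converged = %s\n",
              x$sigma_b, x$sigma_e, x$loglik, x$converged))
  print(round(x$beta, 4))
  invisible(x)
}

# ---- small-sample denominator df ----

#' Small-sample denominator degrees of freedom for a contrast
#'
#' Kenward-Roger-style adjusted denominator df computed by
#' Satterthwaite moment matching on the auxiliary *uncensored* normal LME
#' with the fit's design and variance estimates: df = 2 (L'
#' Phi L)^2 / Var(L' Phi(theta-hat) L), with the variance-component
#' covariance taken from the REML-type expected information. For censored
#' fits this is an approximation on the balanced uncensored design, recorded
#' in the fit metadata. For a balanced random-intercept design and a
#' between-subject contrast it reproduces the exact ANOVA value
#' n_subjects - n_groups.
#'
#' @param fit a `censored_lme`.
#' @param L contrast vector (length = number of fixed effects).
#' @return denominator df (> 0, capped at n_obs - rank(X)).
#' @export
approximate_df <- function(fit, L) {
  satterthwaite_df(fit$X, fit$subject, fit$sigma_b, fit$sigma_e, L)
}

satterthwaite_df <- function(X, subj, sigma_b, sigma_e, L) {
  p <- ncol(X)
  stopifnot(length(L) == p)
  sb2 <- sigma_b^2
  se2 <- sigma_e^2
  XtWX <- matrix(0, p, p)
  U <- list(matrix(0, p, p), matrix(0, p, p))
  T3 <- list(list(matrix(0, p, p), matrix(0, p, p)),
             list(matrix(0, p, p), matrix(0, p, p)))
  t1 <- matrix(0, 2, 2)
  for (lev in levels(subj)) {
    idx <- which(subj == lev)
    n_i <- length(idx)
    Xi <- X[idx, , drop = FALSE]
    cshr <- sb2 / (se2 + n_i * sb2)
    W <- (diag(n_i) - matrix(cshr, n_i, n_i)) / se2
    A <- list(matrix(1, n_i, n_i), diag(n_i))  # dV/dsigma_b2 = J, dV/dsigma_e2 = I
    XtWX <- XtWX + crossprod(Xi, W %*% Xi)
    for (a in 1:2) {
      WA <- W %*% A[[a]]
      U[[a]] <- U[[a]] + crossprod(Xi, WA %*% W %*% Xi)
      for (b in 1:2) {
        WB <- W %*% A[[b]]
        t1[a, b] <- t1[a, b] + sum(diag(WA %*% WB))
        T3[[a]][[b]] <- T3[[a]][[b]] + crossprod(Xi, WA %*% WB %*% W %*% Xi)
      }
    }
  }
  Phi <- solve(XtWX)
  K <- matrix(0, 2, 2)
  for (a in 1:2) for (b in 1:2) {
    K[a, b] <- t1[a, b] -
      sum(diag(Phi %*% (T3[[a]][[b]] + T3[[b]][[a]]))) +
      sum(diag(Phi %*% U[[a]] %*% Phi %*% U[[b]]))
  }
  A_vc <- 2 * solve(K)
  f <- drop(t(L) %*% Phi %*% L)
  g <- vapply(1:2, function(a) drop(t(L) %*% Phi %*% U[[a]] %*% Phi %*% L), 0)
  den <- drop(t(g) %*% A_vc %*% g)
  df <- if (den <= 0) Inf else 2 * f^2 / den
  rk <- qr(X)$rank
  max(1, min(df, nrow(X) - rk))
}

# ---- ratio time courses ----

#' Responder / non-responder geometric-mean-ratio time course
#'
#' For each timepoint, forms the responder-minus-non-responder contrast of
#' the fixed effects, exponentiates it into a geometric-mean ratio, and
#' attaches a Wald test against a t reference with small-sample denominator
#' df from [approximate_df()]. Timepoints with fewer than 2 uncensored
#' observations are dropped with a warning.
#'
#' @param fit a converged `censored_lme` whose fixed effects involve
#'   `responder` and `timepoint`.
#' @param level confidence level.
#' @return data.frame: timepoint, log_ratio, ratio, ci_lo, ci_hi, se, df, p.
#' @export
wald_ratio_timecourse <- function(fit, level = 0.95) {
  if (!isTRUE(fit$converged))
    stop("wald_ratio_timecourse requires a converged fit", call. = FALSE)
  tps <- fit$xlevels[["timepoint"]]
  if (is.null(tps)) stop("fit has no 'timepoint' factor", call. = FALSE)
  keep <- tps
  if (!is.null(fit$timepoint_uncensored)) {
    low <- names(fit$timepoint_uncensored)[fit$timepoint_uncensored < 2]
    if (length(low)) {
      warning("dropping timepoint(s) with < 2 uncensored observations: ",
              paste(low, collapse = ", "))
      keep <- setdiff(tps, low)
    }
  }
  rows <- lapply(keep, function(tp) {
    nd <- data.frame(responder = c(TRUE, FALSE),
                     timepoint = factor(tp, levels = tps))
    M <- stats::model.matrix(fit$fixed, nd)
    L <- drop(M[1, ] - M[2, ])
    contrast_wald(fit, L, level, label = tp)
  })
  out <- do.call(rbind, rows)
  row.names(out) <- NULL
  out
}

contrast_wald <- function(fit, L, level = 0.95, label = NA_character_) {
  if (all(L == 0) || anyNA(L)) stop("singular or undefined contrast", call. = FALSE)
  est <- drop(sum(L * fit$beta))
  v <- drop(t(L) %*% fit$vcov %*% L)
  if (!is.finite(v) || v < 0) stop("singular contrast covariance", call. = FALSE)
  se <- sqrt(v)
  df <- approximate_df(fit, L)
  tstat <- if (se > 0) est / se else sign(est) * Inf
  pval <- 2 * stats::pt(-abs(tstat), df)
  q <- stats::qt(1 - (1 - level) / 2, df)
  data.frame(
    timepoint = label, log_ratio = est, ratio = exp(est),
    ci_lo = exp(est - q * se), ci_hi = exp(est + q * se),
    se = se, df = df, p = pval, stringsAsFactors = FALSE
  )
}

#' Per-analyte censored-LME ratio analysis
#'
#' Fits the responder x timepoint censored LME per analyte and assembles the
#' ratio time courses (heatmap-ready via [ratio_matrix()]).
#'
#' @param cytokines long cytokine table (patient_id, analyte, timepoint,
#'   value, lloq, censored).
#' @param patients patient table providing `responder`.
#' @param analytes analytes to fit (default: all present).
#' @param ... passed to [fit_censored_lme()].
#' @return list with `ratios` (stacked data.frame incl. `analyte`) and
#'   `fits` (named list of `censored_lme`).
#' @export
cytokine_ratio_analysis <- function(cytokines, patients,
                                    analytes = unique(cytokines$analyte), ...) {
  grid <- cytokine_grid()
  fits <- list()
  ratios <- list()
  for (a in analytes) {
    d <- cytokines[cytokines$analyte == a, , drop = FALSE]
    d$responder <- patients$responder[match(d$patient_id, patients$patient_id)]
    lev <- intersect(grid$timepoint, unique(d$timepoint))
    d$timepoint <- factor(d$timepoint, levels = lev)
    fit <- try(fit_censored_lme(d, ...), silent = TRUE)
    if (inherits(fit, "try-error")) next
    fits[[a]] <- fit
    rt <- try(suppressWarnings(wald_ratio_timecourse(fit)), silent = TRUE)
    if (inherits(rt, "try-error")) next
    rt$analyte <- a
    rt$day <- grid$day[match(rt$timepoint, grid$timepoint)]
    ratios[[a]] <- rt
  }
  list(ratios = if (length(ratios)) do.call(rbind, ratios) else NULL,
       fits = fits)
}

#' Analyte x timepoint ratio matrix
#'
#' Reshapes [cytokine_ratio_analysis()] output into the heatmap-ready matrix
#' of responder/non-responder geometric-mean ratios.
#'
#' @param ratios stacked ratio data.frame with `analyte`, `timepoint`,
#'   `ratio`.
#' @return numeric matrix, analytes in rows, grid timepoints in columns.
#' @export
ratio_matrix <- function(ratios) {
  tps <- intersect(cytokine_grid()$timepoint, unique(ratios$timepoint))
  an <- unique(ratios$analyte)
  m <- matrix(NA_real_, length(an), length(tps), dimnames = list(an, tps))
  for (i in seq_len(nrow(ratios)))
    m[ratios$analyte[i], as.character(ratios$timepoint[i])] <- ratios$ratio[i]
  m
}
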