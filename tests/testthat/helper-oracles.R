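# Independent oracles used to check package computations. These are written
# from first principles (enumeration, EM, grid search, direct formulas) and
# never call the code paths they verify.

# --- EM algorithm for the normal random-intercept LME (ML) ---------------
em_lme_oracle <- function(y, X, subject, maxit = 2000, tol = 1e-10) {
  subject <- factor(subject)
  si <- as.integer(subject)
  n_i <- tabulate(si)
  beta <- stats::lm.fit(X, y)$coefficients
  sb2 <- 0.5 * stats::var(rowsum(y - X %*% beta, si)[, 1] / n_i)
  se2 <- stats::var(y - drop(X %*% beta))
  ll_old <- -Inf
  for (it in seq_len(maxit)) {
    r <- y - drop(X %*% beta)
    sums <- rowsum(r, si)[, 1]
    shrink <- sb2 / (se2 + n_i * sb2)
    m <- shrink * sums
    v <- sb2 * se2 / (se2 + n_i * sb2)
    beta <- stats::lm.fit(X, y - m[si])$coefficients
    r2 <- y - drop(X %*% beta)
    sums2 <- rowsum(r2, si)[, 1]
    m <- (sb2 / (se2 + n_i * sb2)) * sums2
    sb2 <- mean(m^2 + v)
    se2 <- mean((r2 - m[si])^2 + v[si])
    ll <- em_lme_loglik(y, X, si, n_i, beta, sb2, se2)
    if (abs(ll - ll_old) < tol) break
    ll_old <- ll
  }
  list(beta = beta, sigma_b = sqrt(sb2), sigma_e = sqrt(se2), loglik = ll)
}

em_lme_loglik <- function(y, X, si, n_i, beta, sb2, se2) {
  r <- y - drop(X %*% beta)
  ll <- 0
  for (i in seq_along(n_i)) {
    ri <- r[si == i]
    ni <- n_i[i]
    # log det and quadratic form of se2*I + sb2*J via Sherman-Morrison
    logdet <- (ni - 1) * log(se2) + log(se2 + ni * sb2)
    quad <- sum(ri^2) / se2 - sb2 * sum(ri)^2 / (se2 * (se2 + ni * sb2))
    ll <- ll - 0.5 * (ni * log(2 * pi) + logdet + quad)
  }
  ll
}

# --- Cox partial likelihood (no ties) grid/golden-section oracle ----------
cox_oracle <- function(time, event, x) {
  stopifnot(!anyDuplicated(time[event == 1]))
  pl <- function(beta) {
    s <- 0
    for (i in which(event == 1)) {
      risk <- time >= time[i]
      s <- s + x[i] * beta - log(sum(exp(x[risk] * beta)))
    }
    s
  }
  stats::optimize(pl, c(-20, 20), maximum = TRUE, tol = 1e-10)$maximum
}

# --- Wilcoxon exact enumeration oracle -----------------------------------
wilcoxon_oracle <- function(x, y) {
  m <- length(x); n <- length(y)
  pool <- c(x, y)
  stopifnot(!anyDuplicated(pool))
  rk <- rank(pool)
  u_obs <- sum(rk[seq_len(m)]) - m * (m + 1) / 2
  combos <- utils::combn(m + n, m)
  u_all <- apply(combos, 2, function(idx) sum(rk[idx]) - m * (m + 1) / 2)
  p <- 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs))
  list(U = u_obs, p = min(1, p))
}

# --- moderated-t shrinkage oracle (moment matching on log variances) ------
trigamma_inverse_oracle <- function(x) {
  y <- 0.5 + 1 / x
  for (i in 1:75) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2)
    y <- y + dif
    if (max(abs(dif / y)) < 1e-12) break
  }
  y
}

moderated_t_oracle <- function(mat, labels) {
  g <- as.numeric(labels)
  n <- ncol(mat)
  t_out <- numeric(nrow(mat))
  s2 <- numeric(nrow(mat))
  coefs <- numeric(nrow(mat))
  for (i in seq_len(nrow(mat))) {
    fit <- stats::lm(mat[i, ] ~ g)
    coefs[i] <- stats::coef(fit)[2]
    s2[i] <- sum(stats::residuals(fit)^2) / (n - 2)
  }
  dg <- n - 2
  z <- log(pmax(s2, 1e-5 * stats::median(s2)))
  e <- z - digamma(dg / 2) + log(dg / 2)
  emean <- mean(e)
  evar <- sum((e - emean)^2) / (length(e) - 1) - trigamma(dg / 2)
  if (evar > 0) {
    d0 <- 2 * trigamma_inverse_oracle(evar)
    s0_2 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s0_2 <- mean(s2)
  }
  var_post <- if (is.finite(d0)) (d0 * s0_2 + dg * s2) / (d0 + dg) else rep(s0_2, length(s2))
  sx <- sum((g - mean(g))^2)
  se_unscaled <- sqrt(1 / sx)
  list(t = coefs / (se_unscaled * sqrt(var_post)), d0 = d0, s0_2 = s0_2)
}

# --- Clopper-Pearson bisection on binomial tail sums ----------------------
cp_bisect_oracle <- function(k, n, level = 0.95) {
  a <- (1 - level) / 2
  upper_tail <- function(p) sum(stats::dbinom(k:n, n, p))   # P(X >= k)
  lower_tail <- function(p) sum(stats::dbinom(0:k, n, p))   # P(X <= k)
  lo <- if (k == 0) 0 else {
    # P(X >= k | p) increases in p; solve = a
    l <- 0; h <- 1
    for (i in 1:200) {
      mid <- (l + h) / 2
      if (upper_tail(mid) > a) h <- mid else l <- mid
    }
    (l + h) / 2
  }
  hi <- if (k == n) 1 else {
    # P(X <= k | p) decreases in p; solve = a
    l <- 0; h <- 1
    for (i in 1:200) {
      mid <- (l + h) / 2
      if (lower_tail(mid) > a) l <- mid else h <- mid
    }
    (l + h) / 2
  }
  c(lo, hi)
}

# --- small expression-experiment builders ---------------------------------
make_toy_exp <- function() {
  counts <- rbind(E1 = c(50, 200), H1 = c(20, 80),
                  P1 = c(100, 400), P2 = c(100, 400),
                  N1 = c(2, 8), N2 = c(4, 16))
  genes <- data.frame(
    gene = rownames(counts),
    probe_class = c("Endogenous", "Housekeeping", "Positive", "Positive",
                    "Negative", "Negative"),
    panel = "toy", stringsAsFactors = FALSE)
  samples <- data.frame(sample_id = c("s1", "s2"), patient_id = c("p1", "p2"),
                        timepoint = "pre", responder = c(TRUE, FALSE),
                        stringsAsFactors = FALSE)
  expression_experiment(counts, genes, samples)
}

make_null_exp <- function(seed, n_genes = 120, n_samp = 16) {
  set.seed(seed)
  counts <- matrix(stats::rnbinom(n_genes * n_samp, size = 15,
                                  mu = 2^stats::rnorm(n_genes, 7, 1.5)), n_genes)
  counts <- rbind(
    counts,
    matrix(stats::rnbinom(6 * n_samp, size = 15, mu = 2^10), 6),
    matrix(stats::rnbinom(4 * n_samp, size = 15, mu = 2^c(12, 10, 8, 6)), 4),
    matrix(stats::rpois(6 * n_samp, 2), 6))
  genes <- data.frame(
    gene = sprintf("g%03d", seq_len(nrow(counts))),
    probe_class = rep(c("Endogenous", "Housekeeping", "Positive", "Negative"),
                      c(n_genes, 6, 4, 6)),
    panel = "p", stringsAsFactors = FALSE)
  samples <- data.frame(
    sample_id = paste0("s", seq_len(n_samp)),
    patient_id = paste0("s", seq_len(n_samp)),
    timepoint = "pre",
    responder = rep(c(TRUE, FALSE), each = ceiling(n_samp / 2))[seq_len(n_samp)],
    stringsAsFactors = FALSE)
  normalize_counts(expression_experiment(counts, genes, samples))
}

# one flow sample in the long-table layout
make_flow_sample <- function(sid, viable1 = 6e4, viable2 = 6e4,
                             cd4_pent = 200, cd8_pent = 2000,
                             cd4_freq = cd4_pent / 3e4, cd8_freq = cd8_pent / 2e4,
                             mem8 = c(100, 100, 500, 800, 500),
                             mem4 = c(40, 20, 60, 50, 30)) {
  phenos <- c("Naive", "TSCM", "CM", "EM", "TEMRA")
  rbind(
    data.frame(sample_id = sid, panel = "Pheno1",
               population = c("CD3", "CD4Pent", "CD8Pent"),
               parent = c(NA, "CD3", "CD3"),
               count = c(viable1, cd4_pent, cd8_pent),
               freq_of_parent = c(NA, cd4_freq, cd8_freq),
               stringsAsFactors = FALSE),
    data.frame(sample_id = sid, panel = "Pheno1",
               population = c(paste0("CD8Pent_", phenos), paste0("CD4Pent_", phenos)),
               parent = rep(c("CD8Pent", "CD4Pent"), each = 5),
               count = c(mem8, mem4),
               freq_of_parent = c(mem8 / max(cd8_pent, 1), mem4 / max(cd4_pent, 1)),
               stringsAsFactors = FALSE),
    data.frame(sample_id = sid, panel = "Pheno2",
               population = c("CD3", "CD4Pent", "CD8Pent"),
               parent = c(NA, "CD3", "CD3"),
               count = c(viable2, cd4_pent, cd8_pent),
               freq_of_parent = c(NA, cd4_freq, cd8_freq),
               stringsAsFactors = FALSE)
  )
}

toy_noise <- function(cd4 = 0.001, cd8 = 0.001) {
  data.frame(population = c("CD4Pent", "CD8Pent"),
             max_negative_control_freq = c(cd4, cd8),
             stringsAsFactors = FALSE)
}

# balanced longitudinal cytokine-style dataset with known effects
sim_lme_data <- function(seed, n = 40, tps = 8, sigma_b = 0.5, sigma_e = 0.5,
                         resp_eff = c(0, .3, .6, .9, .6, .4, .2, .1),
                         time_eff = c(0, .2, .4, .6, .4, .2, .1, 0),
                         cens_q = 0.25) {
  set.seed(seed)
  lv <- paste0("t", seq_len(tps))
  d <- expand.grid(patient_id = seq_len(n), timepoint = lv,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  d$timepoint <- factor(d$timepoint, levels = lv)
  d$responder <- d$patient_id <= n / 2
  mu <- 1 + time_eff[as.integer(d$timepoint)] +
    resp_eff[as.integer(d$timepoint)] * d$responder
  y <- mu + stats::rnorm(n, 0, sigma_b)[d$patient_id] +
    stats::rnorm(nrow(d), 0, sigma_e)
  lloq <- if (cens_q > 0) exp(stats::quantile(y, cens_q)) else 1e-12
  d$value <- exp(y)
  d$censored <- d$value < lloq
  d$value[d$censored] <- lloq
  d$lloq <- lloq
  d
}
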