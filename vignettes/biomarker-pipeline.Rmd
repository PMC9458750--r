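---
title: "Models and methods behind the tcrbm biomarker pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind the tcrbm biomarker pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tcrbm)
```

`tcrbm` analyses the biomarker data streams of an engineered TCR T-cell
therapy trial: the infused product's flow-cytometric phenotype, transgene
qPCR expansion in blood, longitudinal serum cytokines with assay
quantification limits, tumour expression counts with control probes, and the
trial's efficacy endpoints. This vignette explains the models, the tunable
parameters and their defaults, the numerical choices, and what the
synthetic-trial generator does and does not emulate.

## The synthetic trial generator

Real patient-level data from these trials is controlled-access, so every
stage of the pipeline is developed and validated against
`simulate_trial(sim_config())`, which generates a virtual trial with known
ground truth. The defaults encode the study conditions the pipeline targets:

* **Patients.** 45 infused (mITT-style) subjects allocated to four cohorts
  with weights 12/13/5/15; cohorts 1–2 receive standard
  fludarabine+cyclophosphamide lymphodepletion (LDR), cohort 3
  cyclophosphamide only, cohort 4 a reduced fludarabine regimen. Body
  weight is log-normal around 70 kg (floored at 40 kg, where the protocol
  dose rule applies) and the transduced cell dose is log-normal around
  3×10⁹ cells, clamped to the protocol window [1×10⁹, 6×10⁹] (target
  5×10⁹).
* **Expansion and response.** Log peak expansion follows
  log Cmax = α + β_dose·log(dose/kg ÷ 4×10⁷) + β_LDR + ε with β_dose = 1,
  β_LDR = 1 (standard), 0.4 (reduced), 0 (cyclophosphamide-only) and
  ε ~ N(0, 0.8²); the observed series is Cmax times a fixed rise/decay
  shape peaking at day 7, with 25% multiplicative observation noise and a
  qPCR floor of 50 copies/µg reported as 0. Responder status is Bernoulli
  with logit linear in log Cmax, calibrated to an overall response rate
  near one third — so dose/kg and standard LDR raise response probability
  *through* expansion, which is the causal chain the correlate analyses
  probe. PFS and OS are exponential with log-hazard linear in log Cmax and
  administrative censoring at 2 and 3 years.
* **Cytokines.** For each analyte, log concentration is
  baseline + time effect + responder effect × responder + subject intercept
  (σ_b = 0.5) + residual (σ_e = 0.6) on a fixed 10-point grid (baseline,
  day 0 pre-infusion, days 1–7, weeks 2–8). Responder effects place an
  IL-15 elevation already at day 0 (the post-lymphodepletion, pre-infusion
  sample) and IFNγ/IL-6/IL-2Rα peaks around day 4. The study does not
  publish per-analyte LLOQs, so the defaults put most analytes ~1.2 log
  units above their LLOQ while GM-CSF and IL-17A sit below it more than
  half the time, reproducing the reported heavy censoring of those two;
  all LLOQs are configurable, none is inferred from data.
* **Flow.** One product sample per patient measured in two panels; memory
  composition of CD8+Pentamer+ cells is Dirichlet around a
  responder-specific simplex (EM 28% in responders vs 12% in
  non-responders, matching the reported ~2× product difference); six
  healthy-donor negative-control stains define the flooring noise levels.
* **Expression.** 200 endogenous probes (containing a bundled toy gene-set
  collection), 10 housekeeping, 6 positive (titration ladder) and 8
  negative probes; counts are negative binomial (size 15) around
  log-normal gene means with a per-sample lane factor applied to *all*
  probe classes — exactly the nuisance the normalization must remove.
  Progression samples shift the macrophage set by −1 log2; non-responder
  pre-infusion samples shift the IFN-downstream set by +1 log2. Ten
  pre-infusion and five progression samples (three paired) mirror the
  study's biopsy availability.

What the generator deliberately does **not** emulate: event-level FCS data
(only gated count tables), assay chemistry and plate effects, informative
dropout, correlated multi-analyte cytokine dynamics, batch structure in the
expression data, and real pathway collections (the bundled GMT is a labelled
synthetic stand-in for KEGG/GO/REACTOME/MSigDB). Passing tests therefore
demonstrate the statistical machinery is correct under the declared
generative model, not that any specific biological conclusion transfers to
real data.

## Flow phenotyping

Samples with fewer than 5000 viable CD3+ cells in *either* panel are
removed (a 5000-cell sample survives; the rule is strict inequality).
For each pentamer parent gate separately, a parent frequency below the
noise level — the maximum frequency seen in healthy-donor negative
controls — is floored: parent count and frequency set to 0, child memory
gates set to missing. Flooring compares frequencies (not counts), never
increases a value, is idempotent, and missing children propagate as missing
into downstream rank tests. The transduced-cell arithmetic is exact:
the CD4/CD8 pentamer split normalizes the two pentamer counts to sum to 1,
and phenotype cell numbers are split × total transduced cells in the
infused product × frequency-of-parent, so a phenotype partition conserves
the parent total. "Total transduced cells" is the infused transduced cell
dose, which makes the output the infused cells/kg quantity the correlate
analyses use.

## Expansion kinetics

Cmax is the maximum over post-infusion (day > 0) points with ties broken to
the earliest day; the window is unrestricted because the source analyses do
not bound it (flagged in output docs). AUC day 0–28 is the linear trapezoid
on the copies scale — no log transform, no extrapolation beyond observed
days; a series crossing day 28 is interpolated to close the integral exactly
at the boundary. Values below the qPCR detection floor enter the AUC as 0
but are treated as missing in log-scale regressions, which avoids both −∞
and an invented imputation limit.

## The left-censored mixed model

For one analyte, log concentration y_ij follows

y_ij = x_ij'β + b_i + e_ij,  b_i ~ N(0, σ_b²),  e_ij ~ N(0, σ_e²),

with x the responder × timepoint design (time categorical). A value below
its LLOQ is left-censored: its contribution to the likelihood is
Φ((log LLOQ − x'β − b_i)/σ_e) rather than the normal density. The marginal
likelihood integrates the random intercept per subject:

L_i = ∫ φ(b; 0, σ_b) ∏_obs φ(y_ij − x'β − b; 0, σ_e) ∏_cens Φ(·) db.

Numerical choices:

* **Branching rule.** With ≤1 censored value the model is fit as an exact
  normal LME by `lme4::lmer` (ML), matching the source analysis convention;
  with ≥2 the censored likelihood is used.
* **Quadrature.** The integral is one-dimensional (random intercept only;
  the study's AR-1 sensitivity fits did not change conclusions, so only
  independence errors are implemented). It is evaluated with 30-node
  Gauss–Hermite quadrature adapted per subject: centres and scales are the
  posterior mean/SD of b_i from a pilot normal LME fit (censored values
  taken at the LLOQ) and then held fixed, which keeps the approximated
  objective smooth. With no censoring the integrand is Gaussian and the
  adapted rule is exact, so the censored log-likelihood *equals* the
  normal-LME log-likelihood — a tested invariant.
* **Optimizer.** Joint quasi-Newton (L-BFGS-B) on (β, log σ_b, log σ_e)
  with an analytic gradient and three deterministic starts (the pilot
  estimates and ±0.5/∓0.3 perturbations of the log variance components) to
  guard against local maxima; convergence requires optimizer success plus a
  small final gradient norm. Joint quasi-Newton was preferred over profiling
  the two variance parameters because the analytic gradient makes the joint
  problem fast and the two approaches share stationary points.
* **Uncertainty.** β covariance from the inverse observed information
  (central differences of the analytic gradient).
* **Denominator df.** Small-sample Wald tests use Kenward–Roger-style
  adjusted df computed by Satterthwaite moment matching on the auxiliary
  *uncensored* normal LME with the same design and the fitted variances,
  with the variance-component covariance from the REML-type expected
  information. This is an approximation for censored fits (recorded in the
  fit method metadata); for a balanced random-intercept design and a
  between-subject contrast it reproduces the exact ANOVA value
  n_subjects − n_groups, and it is capped at N − rank(X).
* **Reporting.** Natural logs internally; contrasts are exponentiated into
  responder/non-responder geometric-mean ratios so the log base is
  unobservable. Timepoints with fewer than two uncensored observations are
  dropped from the ratio table with a warning rather than extrapolated.
  "Treatment" in the interaction is responder status (the ratio figures
  compare responders to non-responders); cohort can be added as a covariate
  through the model formula if needed.

## Expression analysis

Normalization follows the fixed nCounter recipe, per panel: (1) scale each
sample by mean(g)/g_s where g_s is its positive-control geometric mean;
(2) subtract the sample's negative-control mean + 2 SD from Endogenous and
Housekeeping counts, flooring at 0; (3) scale Endogenous counts by
mean(h)/h_s with h_s the housekeeping geometric mean; (4) round half away
from zero and take log2 after flooring values below 1 to 1 (so
background-zero genes map to 0 — one of several possible zero dialects;
the choice is recorded in the output metadata and results are comparable
only within-dialect). The reference level in steps 1 and 3 is the
arithmetic mean across samples of per-sample geometric means. Because that
reference is itself a function of the data, rescaling one sample is undone
exactly *up to one factor shared by the whole matrix*: scale factors that
preserve the positive-control reference mean leave the output
entry-for-entry identical, and arbitrary factors leave every entry on a
single common ratio. The tests assert both exact statements; an
entry-identical guarantee under arbitrary per-sample scaling is
mathematically impossible with a data-dependent reference mean, and the
dialect-faithful reference was kept in preference to inventing a fixed one.

Group comparisons use limma's moderated t: per-gene variances are shrunk to
s̃² = (d₀s₀² + d_g s_g²)/(d₀ + d_g) with the prior (d₀, s₀²) from moment
matching on log sample variances, and t̃ referred to d₀ + d_g df; d₀ → 0
recovers the ordinary t (exposed via the `prior_df` argument, used by the
tests). Paired pre/progression comparisons reuse the mixed-model machinery
with censoring disabled (per-gene fits, plus a set-average convenience
wrapper — both are provided because the source analyses do not state which
aggregation their set-level figures used, and both are labelled). Per-gene
PFS models are single-covariate Cox fits with Efron ties; monotone
likelihoods are flagged and capped rather than reported as finite estimates.

Gene-set inference is permutation-based, with sample-label permutation for
both tests because both statistics are defined against a grouping: the
global significance statistic √(Σ_{g∈set} t_g²) and the competitive Fisher
odds ratio ad/(bc) of set membership against nominal significance
(p < 0.05; Haldane 0.5 correction only when a cell is empty; the Fisher
exact p is the permutation objective). Moderated t is recomputed inside
every permutation, for consistency with the observed statistic. p-values
use the add-one estimator (1 + #{at least as extreme})/(B + 1) with
B = 5000 by default; when fewer than 20 distinct label assignments exist
the null is enumerated exactly. Sets enter only if they have ≥5
overlapping non-constant genes on the panel covering ≥50% of the original
set. No multiple-testing adjustment is applied anywhere: all p-values are
nominal and descriptive, matching the source convention.

## Efficacy and correlate statistics

Clopper–Pearson bounds invert the exact binomial tails through the beta
quantile closed form; display rounding is half away from zero (2 decimals
for bounds, whole percent for ORR), which is required to reproduce printed
efficacy tables. The Wilcoxon rank-sum test uses exact enumeration for
pooled samples of at most 20 without ties and the tie-corrected,
continuity-corrected normal approximation otherwise. Spearman tests use the
t approximation on n − 2 df. Median regression minimizes absolute
deviations — closed form (the sample median) for the intercept-only case,
ε-smoothed iteratively reweighted least squares otherwise — and its
two-sided p-value is the sign-crossing bootstrap fraction
2·min(frac(coef* ≤ 0), frac(coef* ≥ 0)) clipped to [1/B, 1], chosen because
the source does not state a convention (a normal-approximation alternative
would be straightforward but is not the default). Kaplan–Meier medians are
read off as the first time the survival estimate drops to ≤ 0.5 (the lower
central order statistic under no censoring, even n), with
Brookmeyer–Crowley-style confidence bounds from the survfit band — the
source does not name its median CI method, so the choice is labelled.

## Problem sizes and determinism

Every stochastic routine takes an explicit seed and is reproducible
byte-for-byte; the pipeline manifest records file digests so reruns can be
audited. The validation suite sizes its simulations to be decisive yet
routine on a laptop: 200 replicates of a 40-subject × 8-timepoint censored
LME for bias and coverage, 500 label-independent null sets (25 independent
datasets × 20 sets, B = 500) for permutation type-I error, 100 seeds for
the flow effect-recovery property, 1000 null analytes for Wald calibration,
and 20 full synthetic trials for the end-to-end directional check.

## Known limitations

The censored-path Wald machinery borrows its denominator df from the
uncensored auxiliary model; with heavy censoring (well beyond the ~25%
regime validated here) both the df and the observed-information covariance
become approximate together, and coverage should be re-checked by
simulation before trusting nominal levels. The EM-free quadrature fit
assumes a scalar random intercept; random slopes and cross-analyte models
are out of scope. The competitive Fisher test conditions on a fixed 0.05
significance threshold, so its permutation p is discrete at small gene
counts. LAD regression via smoothed IRLS converges to an ε-neighbourhood of
the exact LAD solution, which is ample for bootstrap inference but not for
exact-solution comparisons.
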