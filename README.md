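# tcrbm — biomarker correlates of TCR T-cell therapy

`tcrbm` implements the complete biomarker-correlates analysis chain for an
engineered TCR T-cell therapy trial in a solid tumour (the setting is an
NY-ESO-1-directed TCR product, lete-cel, in synovial sarcoma): product flow
cytometry, transgene expansion kinetics, longitudinal serum cytokines,
tumour expression profiling, and efficacy statistics. Patient-level data
from such trials is controlled-access, so the package ships a
synthetic-trial generator that reproduces the statistical structure of every
data domain with known ground truth; every analysis stage is exercised and
validated against that generator.

## Who it is for

Biostatisticians and translational scientists analysing cell-therapy trials
who need reusable, tested implementations of the assay-specific statistics
these studies use:

* **Flow phenotyping** — viability QC (samples with fewer than 5000 viable
  CD3+ cells in either panel are removed), negative-control flooring of
  pentamer gates, the CD4/CD8 pentamer split
  `%CD4+Pent+ = nCD4Pent / (nCD4Pent + nCD8Pent)`, and absolute transduced
  cells per memory phenotype:
  `n_cells = split × total transduced × %phenotype`, reported per kg.
* **Expansion kinetics** — Cmax (peak post-infusion transgene copies/µg
  genomic DNA, earliest-day tie-break), trapezoidal AUC over days 0–28
  without extrapolation, and week-4 persistence within a ±3-day window.
* **Left-censored cytokine mixed models** — log concentration modelled with
  responder × timepoint fixed effects and a random subject intercept; values
  below the LLOQ contribute a normal CDF term to the marginal likelihood,
  which is maximized with adaptive Gauss–Hermite quadrature (exact normal
  LME via `lme4` when at most one value is censored). Responder/non-responder
  geometric-mean-ratio time courses come with Wald tests on small-sample
  (Kenward–Roger-style, moment-matched) denominator df.
* **nCounter-style expression** — RCC reading/writing, the exact
  normalization recipe (positive-control geometric-mean lane scaling,
  mean + 2 SD negative-control background subtraction, housekeeping
  geometric-mean content normalization, rounding, log2), limma moderated-t
  group comparisons, paired pre/progression mixed models, per-gene Cox PFS
  models, and two permutation gene-set tests: the global significance
  statistic √(Σ t²) and the competitive Fisher odds ratio, both with
  sample-label permutation p-values (study default 5000 permutations) and
  the ≥5-overlapping-non-constant-genes / ≥50%-coverage set filter.
* **Efficacy and correlates** — exact Clopper–Pearson ORR intervals,
  Wilcoxon rank-sum (exact branch for small tie-free samples), Spearman
  tests, bootstrapped least-absolute-deviation (median) regression, logistic
  association, and Kaplan–Meier / log-rank / Cox summaries.

## Worked example

```r
library(tcrbm)

trial <- simulate_trial(sim_config(n_patients = 45, seed = 7))
trial
#> Synthetic TCR T-cell trial dataset
#>   patients:  45 (15 responders)
#>   cytokines: 4500 measurements, 10 analytes (16.3% censored)
#>   flow:      720 gated rows over 45 samples
#>   expansion: 315 qPCR points
#>   expression: 224 probes x 15 samples

# exact Clopper-Pearson interval for 6 responders of 12 patients
cp <- clopper_pearson(6, 12)
sprintf("ORR %.0f%% (%.2f-%.2f)", 100 * cp$orr, cp$ci_low_2dp, cp$ci_high_2dp)
#> "ORR 50% (0.21-0.79)"

# left-censored LME for one cytokine: responder x timepoint + (1 | patient)
d <- trial$cytokines[trial$cytokines$analyte == "IFNg", ]
d$responder <- trial$patients$responder[match(d$patient_id, trial$patients$patient_id)]
d$timepoint <- factor(d$timepoint, levels = cytokine_grid()$timepoint)
fit <- fit_censored_lme(d)
fit
#> Left-censored LME fit (gh_ml): 450 obs, 45 subjects, 10 censored
#>   sigma_b = 0.4978, sigma_e = 0.5575, logLik = -428.435, converged = TRUE

wald_ratio_timecourse(fit)[3:5, c("timepoint", "ratio", "ci_lo", "ci_hi", "p")]
#>   timepoint  ratio  ci_lo  ci_hi     p
#> 3        d1 2.4236 1.5192 3.8665 3e-04
#> 4        d4 4.8882 3.0646 7.7967 0e+00
#> 5        d7 3.5460 2.2232 5.6559 0e+00
```

The ratio column is the responder/non-responder geometric-mean ratio per
timepoint: in this simulated trial (whose generative parameters mirror the
study's observed effects) responders show a 2- to 5-fold IFNγ elevation
over days 1–7 post-infusion, with Wald confidence intervals and nominal
p-values from the t reference with moment-matched denominator df. The full
chain — efficacy table, expansion correlates, phenotype doses, cytokine
ratio heatmap, gene-level and gene-set results, plus a digest manifest —
is produced by `run_pipeline(sim_config(seed = 7), "report_dir")`, and
`inst/scripts/tcrbm.R` exposes the same stages as a small command line.

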