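Package: tcrbm
Title: Biomarker Correlate Analysis for TCR T-Cell Therapy Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for biomarker correlates of engineered TCR
    T-cell therapy in solid tumours, modelled on the assay structure of an
    NY-ESO-1 TCR (lete-cel) trial in synovial sarcoma. Implements
    flow-cytometry product phenotyping with negative-control flooring and
    transduced-cell inference, transgene qPCR expansion kinetics (Cmax, AUC,
    persistence), left-censored longitudinal cytokine mixed models with
    small-sample Wald inference, NanoString-style nCounter count
    normalization with permutation gene-set statistics, and efficacy and
    correlate statistics (exact Clopper-Pearson intervals, rank tests,
    bootstrapped median regression, Kaplan-Meier/log-rank/Cox summaries).
    A synthetic-trial generator emulates the study's data structure so every
    stage is testable without controlled-access patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    lme4,
    limma,
    survival,
    yaml,
    jsonlite,
    fgsea
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
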