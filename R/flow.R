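#' Viability QC filter for flow samples
#'
#' A sample is retained only when it has at least `min_viable` viable CD3+
#' cells in *both* the Pheno1 and Pheno2 panels; samples below the threshold
#' in either panel (strictly fewer than `min_viable`) or missing a panel are
#' removed. Matches the study rule that samples with <5000 viable CD3+ cells
#' in either panel are excluded downstream.
#'
#' @param counts long flow table (sample_id, panel, population, parent,
#'   count, freq_of_parent).
#' @param min_viable minimum viable CD3+ count (default 5000).
#' @return list with `retained` (filtered table), `rejected` (data.frame
#'   sample_id, reason).
#' @export
qc_filter_samples <- function(counts, min_viable = 5000) {
  cd3 <- counts[counts$population == "CD3", c("sample_id", "panel", "count")]
  rejections <- list()
  keep <- character()
  for (sid in unique(counts$sample_id)) {
    v <- cd3[cd3$sample_id == sid, ]
    missing <- setdiff(c("Pheno1", "Pheno2"), v$panel)
    low <- v$panel[v$count < min_viable]
    if (length(missing)) {
      rejections[[sid]] <- sprintf("incomplete: missing panel %s",
                                   paste(missing, collapse = "/"))
    } else if (length(low)) {
      rejections[[sid]] <- sprintf("<%d viable CD3 in %s", min_viable,
                                   paste(low, collapse = "/"))
    } else {
      keep <- c(keep, sid)
    }
  }
  list(
    retained = counts[counts$sample_id %in% keep, , drop = FALSE],
    rejected = data.frame(
      sample_id = names(rejections),
      reason = unlist(rejections, use.names = FALSE),
      stringsAsFactors = FALSE
    )
  )
}

#' Floor pentamer parent gates below the negative-control noise level
#'
#' For each pentamer parent (CD4Pent, CD8Pent, separately) whose
#' frequency-of-parent is strictly below the noise level (the maximum
#' frequency observed in healthy-donor negative-control samples), the parent
#' frequency and count are set to 0 and every child memory-subset gate is set
#' to missing. Other populations are untouched; the operation is idempotent
#' (a floored parent at frequency 0 re-floors to 0).
#'
#' @param sample_counts long flow table rows for one sample.
#' @param noise data.frame (population, max_negative_control_freq) covering
#'   both pentamer parents.
#' @return the sample table with flooring applied.
#' @export
floor_pentamer_frequencies <- function(sample_counts, noise) {
  out <- sample_counts
  for (parent in c("CD4Pent", "CD8Pent")) {
    lev <- noise$max_negative_control_freq[noise$population == parent]
    if (!length(lev) || is.na(lev))
      stop("no noise level available for parent gate ", parent, call. = FALSE)
    pr <- which(out$population == parent)
    if (!length(pr)) next
    floor_rows <- pr[!is.na(out$freq_of_parent[pr]) & out$freq_of_parent[pr] < lev]
    if (length(floor_rows)) {
      out$freq_of_parent[floor_rows] <- 0
      out$count[floor_rows] <- 0
      ch <- which(out$parent == parent &
                    out$panel %in% out$panel[floor_rows])
      out$count[ch] <- NA
      out$freq_of_parent[ch] <- NA
    }
  }
  out
}

#' Infer the CD4/CD8 split of pentamer-positive cells
#'
#' %CD4+Pentamer+ = nCD4Pent / (nCD4Pent + nCD8Pent); %CD8+Pentamer+ is
#' inferred as its complement, so the two fractions sum to exactly 1.
#'
#' @param n_cd4_pent CD3+CD4+Pentamer+ cell count.
#' @param n_cd8_pent CD3+CD8+Pentamer+ cell count.
#' @return named numeric vector c(pct_cd4_pent, pct_cd8_pent).
#' @export
infer_pentamer_split <- function(n_cd4_pent, n_cd8_pent) {
  stopifnot(n_cd4_pent >= 0, n_cd8_pent >= 0)
  tot <- n_cd4_pent + n_cd8_pent
  if (tot <= 0)
    stop("pentamer split undefined: both pentamer counts are zero", call. = FALSE)
  p4 <- n_cd4_pent / tot
  c(pct_cd4_pent = p4, pct_cd8_pent = 1 - p4)
}

#' Absolute transduced cells of one memory phenotype
#'
#' n_cells = split fraction x total transduced cells x phenotype
#' frequency-of-parent; cells/kg divides by body weight. The total transduced
#' cells are the infused transduced cell dose of the product.
#'
#' @param split_fraction pentamer CD4 or CD8 fraction in [0,1].
#' @param total_transduced transduced cells in the infused product (> 0).
#' @param phenotype_fraction frequency of the phenotype among the pentamer
#'   parent, in [0,1] (NA propagates).
#' @param weight_kg body weight (> 0).
#' @return named numeric vector c(n_cells, n_cells_per_kg).
#' @export
transduced_cells_by_phenotype <- function(split_fraction, total_transduced,
                                          phenotype_fraction, weight_kg) {
  stopifnot(split_fraction >= 0, split_fraction <= 1, total_transduced > 0)
  if (weight_kg <= 0) stop("weight_kg must be > 0", call. = FALSE)
  n <- split_fraction * total_transduced * phenotype_fraction
  c(n_cells = n, n_cells_per_kg = n / weight_kg)
}

#' Per-patient phenotype dose table
#'
#' Runs the full flow post-processing for product samples: viability QC,
#' negative-control flooring, pentamer split, and absolute transduced cells
#' per memory phenotype and per kg. Missing (floored) phenotype frequencies
#' propagate as NA.
#'
#' @param counts long flow table for product samples (one sample per
#'   patient, sample_id = `<patient_id>_product`).
#' @param noise negative-control noise table.
#' @param patients patient table (patient_id, weight_kg,
#'   transduced_cell_dose).
#' @param min_viable viability QC threshold.
#' @return data.frame: patient_id, parent, phenotype, n_cells,
#'   n_cells_per_kg; attribute `qc_rejected` lists removed samples.
#' @export
phenotype_dose_table <- function(counts, noise, patients, min_viable = 5000) {
  qc <- qc_filter_samples(counts, min_viable)
  phenos <- c("Naive", "TSCM", "CM", "EM", "TEMRA")
  rows <- list()
  for (sid in unique(qc$retained$sample_id)) {
    sc <- floor_pentamer_frequencies(
      qc$retained[qc$retained$sample_id == sid, , drop = FALSE], noise)
    pid <- sub("_product$", "", sid)
    pt <- patients[patients$patient_id == pid, ]
    if (!nrow(pt)) next
    p1 <- sc[sc$panel == "Pheno1", ]
    n4 <- p1$count[p1$population == "CD4Pent"]
    n8 <- p1$count[p1$population == "CD8Pent"]
    if (!length(n4) || !length(n8) || (isTRUE(n4 + n8 == 0))) next
    split <- infer_pentamer_split(n4, n8)
    for (parent in c("CD4Pent", "CD8Pent")) {
      sf <- if (parent == "CD4Pent") split[["pct_cd4_pent"]] else split[["pct_cd8_pent"]]
      for (ph in phenos) {
        fr <- p1$freq_of_parent[p1$population == paste0(parent, "_", ph)]
        fr <- if (length(fr)) fr else NA_real_
        d <- transduced_cells_by_phenotype(sf, pt$transduced_cell_dose, fr,
                                           pt$weight_kg)
        rows[[length(rows) + 1L]] <- data.frame(
          patient_id = pid, parent = parent, phenotype = ph,
          n_cells = d[["n_cells"]], n_cells_per_kg = d[["n_cells_per_kg"]],
          stringsAsFactors = FALSE
        )
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(patient_id = character(), parent = character(),
               phenotype = character(), n_cells = numeric(),
               n_cells_per_kg = numeric(), stringsAsFactors = FALSE)
  attr(out, "qc_rejected") <- qc$rejected
  out
}
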