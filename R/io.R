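# CSV is written with %.17g formatting for doubles so every table round-trips
# through write/read exactly (base write.csv prints 15 significant digits,
# which can drop the last bit of a double).
write_csv_exact <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) {
      v <- sprintf("%.17g", out[[j]])
      v[is.na(out[[j]])] <- NA
      out[[j]] <- v
    }
  }
  utils::write.csv(out, path, row.names = FALSE, na = "NA")
  invisible(path)
}

read_csv_plain <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write / read a trial dataset as plain-text files
#'
#' Writes `patients.csv`, `cytokines.csv` (long format), `flow_counts.csv`,
#' `noise.csv`, `expansion.csv`, one RCC text file per expression sample plus
#' `samples.csv`, `genesets.gmt`, and `config.yaml`. [read_trial()]
#' reconstructs the dataset (generative ground truth is not persisted).
#'
#' @param trial a `trial_dataset`.
#' @param dir output directory (created if needed).
#' @return `write_trial()` the directory, invisibly; `read_trial()` a
#'   `trial_dataset`.
#' @export
write_trial <- function(trial, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_csv_exact(trial$patients, file.path(dir, "patients.csv"))
  write_csv_exact(trial$cytokines, file.path(dir, "cytokines.csv"))
  write_csv_exact(trial$flow_counts, file.path(dir, "flow_counts.csv"))
  write_csv_exact(trial$noise, file.path(dir, "noise.csv"))
  write_csv_exact(trial$expansion, file.path(dir, "expansion.csv"))
  rcc_dir <- file.path(dir, "rcc")
  dir.create(rcc_dir, showWarnings = FALSE)
  ex <- trial$expression
  for (s in colnames(ex$counts))
    write_rcc(ex, s, file.path(rcc_dir, paste0(s, ".rcc")))
  write_csv_exact(ex$samples, file.path(dir, "samples.csv"))
  write_gmt(trial$genesets, file.path(dir, "genesets.gmt"))
  if (!is.null(trial$config)) write_config(trial$config, file.path(dir, "config.yaml"))
  invisible(dir)
}

#' @rdname write_trial
#' @export
read_trial <- function(dir) {
  samples <- read_csv_plain(file.path(dir, "samples.csv"))
  expr <- read_rcc_dir(file.path(dir, "rcc"), samples)
  cfg_path <- file.path(dir, "config.yaml")
  out <- list(
    patients = read_csv_plain(file.path(dir, "patients.csv")),
    cytokines = read_csv_plain(file.path(dir, "cytokines.csv")),
    flow_counts = read_csv_plain(file.path(dir, "flow_counts.csv")),
    noise = read_csv_plain(file.path(dir, "noise.csv")),
    expansion = read_csv_plain(file.path(dir, "expansion.csv")),
    expression = expr,
    genesets = read_gmt(file.path(dir, "genesets.gmt")),
    config = if (file.exists(cfg_path)) read_config(cfg_path) else NULL,
    truth = NULL
  )
  class(out) <- "trial_dataset"
  out
}

#' Write one sample of an expression experiment as an RCC text file
#'
#' Emits the nCounter RCC section layout (Header, Sample_Attributes,
#' Lane_Attributes, Code_Summary) with CodeClass/Name/Accession/Count rows.
#'
#' @param exp an [expression_experiment()].
#' @param sample_id column of `exp$counts` to write.
#' @param path output file.
#' @export
write_rcc <- function(exp, sample_id, path) {
  stopifnot(sample_id %in% colnames(exp$counts))
  g <- exp$genes
  cnt <- exp$counts[, sample_id]
  lines <- c(
    "<Header>",
    "FileVersion,1.7",
    "SoftwareVersion,4.0.0.3",
    "</Header>",
    "",
    "<Sample_Attributes>",
    paste0("ID,", sample_id),
    paste0("GeneRLF,", g$panel[1]),
    "</Sample_Attributes>",
    "",
    "<Lane_Attributes>",
    "ID,1",
    "</Lane_Attributes>",
    "",
    "<Code_Summary>",
    "CodeClass,Name,Accession,Count",
    sprintf("%s,%s,%s,%d", g$probe_class, g$gene,
            paste0("SYN_", g$gene), as.integer(cnt)),
    "</Code_Summary>"
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read an RCC text file
#'
#' Parses the Header, Sample_Attributes and Code_Summary sections. Probe
#' class is taken from the CodeClass column; counts must be integers.
#'
#' @param path RCC file.
#' @return list with `sample_id`, `panel`, and `codes` (data.frame:
#'   probe_class, gene, accession, count).
#' @export
read_rcc <- function(path) {
  lines <- readLines(path)
  open_cs <- grep("^<Code_Summary>", lines)
  close_cs <- grep("^</Code_Summary>", lines)
  if (length(open_cs) != 1 || length(close_cs) != 1)
    stop(sprintf("RCC parse error in '%s': missing Code_Summary section (line %d)",
                 path, length(lines)), call. = FALSE)
  body <- lines[(open_cs + 1):(close_cs - 1)]
  hdr <- strsplit(body[1], ",")[[1]]
  if (!identical(hdr[c(1, 2, 4)], c("CodeClass", "Name", "Count")))
    stop(sprintf("RCC parse error in '%s': unexpected Code_Summary header (line %d)",
                 path, open_cs + 1), call. = FALSE)
  rows <- strsplit(body[-1], ",")
  cnt_chr <- vapply(rows, `[`, "", 4L)
  cnt <- suppressWarnings(as.integer(cnt_chr))
  if (anyNA(cnt)) {
    bad <- which(is.na(cnt))[1]
    stop(sprintf("RCC parse error in '%s': non-integer count '%s' for probe '%s' (line %d)",
                 path, cnt_chr[bad], rows[[bad]][2], open_cs + 1 + bad),
         call. = FALSE)
  }
  sample_line <- grep("^ID,", lines[grep("^<Sample_Attributes>", lines):length(lines)],
                      value = TRUE)[1]
  panel_line <- grep("^GeneRLF,", lines, value = TRUE)
  list(
    sample_id = sub("^ID,", "", sample_line),
    panel = if (length(panel_line)) sub("^GeneRLF,", "", panel_line[1]) else NA_character_,
    codes = data.frame(
      probe_class = vapply(rows, `[`, "", 1L),
      gene = vapply(rows, `[`, "", 2L),
      accession = vapply(rows, `[`, "", 3L),
      count = cnt,
      stringsAsFactors = FALSE
    )
  )
}

#' Read a directory of RCC files into an expression experiment
#'
#' @param dir directory containing `*.rcc` files.
#' @param samples sample annotation data.frame (sample_id, patient_id,
#'   timepoint, responder); rows are matched to RCC sample IDs.
#' @return an [expression_experiment()] with raw counts.
#' @export
read_rcc_dir <- function(dir, samples) {
  files <- list.files(dir, pattern = "\\.rcc$", full.names = TRUE)
  if (!length(files)) stop("no RCC files in ", dir, call. = FALSE)
  parsed <- lapply(files, read_rcc)
  ids <- vapply(parsed, `[[`, "", "sample_id")
  ref <- parsed[[1]]$codes
  counts <- vapply(parsed, function(p) {
    if (!identical(p$codes$gene, ref$gene))
      stop("RCC files disagree on probe content", call. = FALSE)
    as.numeric(p$codes$count)
  }, numeric(nrow(ref)))
  dimnames(counts) <- list(ref$gene, ids)
  samples <- samples[match(ids, samples$sample_id), , drop = FALSE]
  probe <- data.frame(gene = ref$gene, probe_class = ref$probe_class,
                      panel = parsed[[1]]$panel, stringsAsFactors = FALSE)
  expression_experiment(counts, probe, samples)
}

#' Read / write gene-set collections in GMT format
#'
#' Standard GMT: one set per line, tab-separated name, description, then gene
#' symbols. Reading delegates to `fgsea::gmtPathways`.
#'
#' @param sets named list of character vectors.
#' @param path GMT file.
#' @return `read_gmt()` a named list of character vectors.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, "synthetic_toy_collection", sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_gmt
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}
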