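# Plain-text (TSV) readers and writers for the study file formats.

#' Write a simulated study to TSV files
#'
#' Writes \code{design.tsv}, \code{tpm.tsv} (first column \code{gene_id},
#' then one column per transcript sample), \code{peptides.tsv} (long
#' format) and \code{truth_genes.tsv} (per-gene latent abundances, DE flags
#' and temperature effects, wide over strains) into a directory.
#'
#' @param study list from \code{\link{simulateStudy}}.
#' @param dir output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
writeStudyTsv <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(df, file) {
    path <- file.path(dir, file)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    path
  }
  paths <- c(tsv(study$design, "design.tsv"))
  tpm <- data.frame(gene_id = rownames(study$tpm), study$tpm,
                    check.names = FALSE, stringsAsFactors = FALSE)
  paths <- c(paths, tsv(tpm, "tpm.tsv"),
             tsv(peptideData(study$peptides), "peptides.tsv"))
  tr <- study$truth
  tg <- data.frame(gene_id = tr$genes,
                   latent_transcript = tr$latentTranscript,
                   latent_protein = tr$latentProtein,
                   stringsAsFactors = FALSE)
  for (s in colnames(tr$deFlag)) {
    tg[[paste0("de_", s)]] <- tr$deFlag[, s]
    tg[[paste0("eff_transcript_", s)]] <- tr$effTranscript[, s]
    tg[[paste0("eff_protein_", s)]] <- tr$effProtein[, s]
  }
  paths <- c(paths, tsv(tg, "truth_genes.tsv"))
  invisible(paths)
}

#' Read a sample design table
#' @param path TSV with the columns of \code{\link{simulateDesign}} output.
#' @return data.frame.
#' @export
readDesign <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}

#' Read a TPM matrix
#' @param path TSV whose first column is \code{gene_id}, remaining columns
#'   sample abundances.
#' @return genes x samples numeric matrix.
#' @export
readTpm <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Read a long-format peptide table
#'
#' @param path TSV with columns \code{peptide_id}, \code{gene_ids}
#'   (semicolon-separated), \code{run}, \code{sample_id}, \code{intensity}.
#' @param design design data.frame (protein channels), e.g. from
#'   \code{\link{readDesign}}.
#' @param stage processing stage of the stored intensities.
#' @return A \linkS4class{PeptideExperiment}.
#' @export
readPeptideTable <- function(path, design, stage = "raw") {
  pep <- read.delim(path, stringsAsFactors = FALSE)
  PeptideExperiment(pep, design, stage = stage)
}

#' Read gene-to-GO annotations
#'
#' @param path TSV with columns \code{gene_id} and \code{go_ids}
#'   (semicolon-separated term ids; empty for unannotated genes).
#' @return Named list gene id -> character vector of term ids.
#' @export
readGoAnnotations <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  .checkCols(df, c("gene_id", "go_ids"), "annotation table")
  ann <- strsplit(df$go_ids, ";", fixed = TRUE)
  ann <- lapply(ann, function(x) x[nzchar(x)])
  setNames(ann, df$gene_id)
}

#' Read a ROS measurement table
#' @param path TSV with the columns expected by \code{\link{normalizeRos}}.
#' @return data.frame.
#' @export
readRosTable <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}
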