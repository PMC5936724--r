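# End-to-end convenience wrapper: from a raw peptide table and TPM matrix
# to relative expressions, differential calls, transcript-protein
# regressions and concordance classes.

#' Run the integrated heat-stress analysis
#'
#' Applies the full chain to a (simulated or real) study: log2 + loading
#' correction, per-gene median polish, detection filtering, gene-level
#' summarization; transcript and protein differential expression per
#' strain; absolute transcript-protein regressions per strain and
#' temperature; fold-change regressions per strain; and concordance
#' classification of the differentially expressed proteins.
#'
#' @param study list with \code{tpm}, \code{peptides}
#'   (\linkS4class{PeptideExperiment}, raw), \code{design} and
#'   \code{config} (for strain labels; otherwise strains are taken from the
#'   design), as produced by \code{\link{simulateStudy}}.
#' @param alpha significance threshold for transcript calls.
#' @param fcThreshold protein fold-change threshold.
#' @return A list with elements \code{relexpr}, \code{channelMat},
#'   \code{det} (per strain), \code{depFc} (per strain), \code{depTtest}
#'   (per strain), \code{glm}, \code{absolute} (RegressionResult table),
#'   \code{foldchange} (RegressionResult table), \code{concordance}
#'   (per strain, each with its \code{"summary"} attribute).
#' @examples
#' study <- simulateStudy(SimConfig(nGenes = 120, seed = 2))
#' res <- runHeatStressAnalysis(study)
#' res$absolute
#' @export
runHeatStressAnalysis <- function(study, alpha = 0.05, fcThreshold = 1.2) {
  design <- study$design
  strains <- if (!is.null(study$config)) study$config@strains
             else unique(design$strain)
  temps <- intersect(c("control", "stress"), unique(design$temperature))

  pe <- log2LoadingCorrect(study$peptides)
  pe <- medianPolishGenes(pe)
  pe <- filterDetection(pe)
  relexpr <- summarizeRelExpr(pe)
  channelMat <- proteinChannelMatrix(pe)
  scpm <- proteinScpm(study$peptides)

  det <- lapply(setNames(strains, strains), function(s)
    transcriptDe(study$tpm, design, s, alpha = alpha))
  depFc <- lapply(setNames(strains, strains), function(s)
    proteinFcDe(relexpr, s, fcThreshold = fcThreshold))
  depTtest <- lapply(setNames(strains, strains), function(s)
    proteinTtest(channelMat, strain = s, alpha = alpha))
  glm <- proteinGlm(channelMat, alpha = alpha)

  absolute <- do.call(rbind, lapply(strains, function(s)
    do.call(rbind, lapply(temps, function(tp)
      absoluteCorrelation(study$tpm, scpm, design, s, tp)))))
  foldchange <- do.call(rbind, lapply(strains, function(s)
    foldchangeCorrelation(det[[s]], depFc[[s]], label = s)))
  concordance <- lapply(setNames(strains, strains), function(s)
    classifyConcordance(depFc[[s]], det[[s]]))

  list(relexpr = relexpr, channelMat = channelMat, det = det,
       depFc = depFc, depTtest = depTtest, glm = glm,
       absolute = absolute, foldchange = foldchange,
       concordance = concordance)
}
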