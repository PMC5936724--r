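#' Simulation configuration for synthetic heat-stress studies
#'
#' An S4 class holding every knob of the synthetic multi-omics generator.
#' Defaults describe a study of three anemone strains sampled at a control
#' (25°C) and a stress (32°C) temperature with four biological
#' replicates per strain and temperature, labelled proteomics with two
#' technical replicate channels per biological sample, weak absolute
#' transcript-protein coupling and fully decoupled temperature responses.
#'
#' @slot nGenes number of simulated gene models.
#' @slot strains strain labels.
#' @slot temperatures subset of \code{c("control", "stress")}.
#' @slot nBioReps biological replicates per strain \eqn{\times} temperature.
#' @slot nTechReps technical replicate channels per biological sample.
#' @slot nRuns number of labelled proteomics runs; biological samples are
#'   blocked into runs with both temperatures present in every run.
#' @slot couplingRho latent correlation between log2 transcript and log2
#'   protein abundance, in (-1, 1). The squared value is the expected
#'   no-noise r-squared of the absolute transcript-protein regression.
#' @slot fcCouplingRho correlation between transcript and protein
#'   temperature effects of a differentially expressed gene.
#' @slot deFraction fraction of genes with a temperature effect per strain.
#' @slot effectSizeSd standard deviation (log2) of temperature effects.
#' @slot strainEffectSd standard deviation (log2) of per-gene per-strain
#'   baseline offsets (0 = identical strains at baseline).
#' @slot loadingOffsetSd standard deviation (log2) of per-channel loading
#'   offsets, the artefact removed by loading correction.
#' @slot peptidesPerGene mean of the (shifted Poisson, minimum 1) number of
#'   peptides per gene.
#' @slot peptideEffectSd standard deviation (log2) of per-peptide detection
#'   efficiencies.
#' @slot ambiguousFraction fraction of peptides mapping to more than one
#'   gene model.
#' @slot detectProb per-peptide per-channel detection probability.
#' @slot noiseSdTranscript,noiseSdProtein measurement noise (log2).
#' @slot latentMean,latentSd location and scale (log2) of latent abundances.
#' @slot seed integer seed; identical seed and configuration give
#'   byte-identical simulations.
#' @seealso \code{\link{SimConfig}} for the user-facing constructor.
#' @export
setClass("SimConfig",
  representation(
    nGenes = "integer", strains = "character", temperatures = "character",
    nBioReps = "integer", nTechReps = "integer", nRuns = "integer",
    couplingRho = "numeric", fcCouplingRho = "numeric",
    deFraction = "numeric", effectSizeSd = "numeric",
    strainEffectSd = "numeric", loadingOffsetSd = "numeric",
    peptidesPerGene = "numeric", peptideEffectSd = "numeric",
    ambiguousFraction = "numeric", detectProb = "numeric",
    noiseSdTranscript = "numeric", noiseSdProtein = "numeric",
    latentMean = "numeric", latentSd = "numeric", seed = "integer"))

setValidity("SimConfig", function(object) {
  msg <- character()
  cnt <- c(nGenes = object@nGenes, nBioReps = object@nBioReps,
           nTechReps = object@nTechReps, nRuns = object@nRuns)
  if (any(cnt < 1L)) msg <- c(msg, "all counts must be >= 1")
  if (length(object@strains) < 1L || anyDuplicated(object@strains))
    msg <- c(msg, "strains must be a non-empty set of unique labels")
  if (!all(object@temperatures %in% c("control", "stress")) ||
      length(object@temperatures) < 1L)
    msg <- c(msg, "temperatures must be a non-empty subset of control/stress")
  sds <- c(object@effectSizeSd, object@strainEffectSd, object@loadingOffsetSd,
           object@peptideEffectSd, object@noiseSdTranscript,
           object@noiseSdProtein, object@latentSd)
  if (any(sds < 0)) msg <- c(msg, "all standard deviations must be >= 0")
  fr <- c(object@deFraction, object@ambiguousFraction, object@detectProb)
  if (any(fr < 0 | fr > 1))
    msg <- c(msg, "fractions and probabilities must lie in [0, 1]")
  if (abs(object@couplingRho) >= 1 || abs(object@fcCouplingRho) >= 1)
    msg <- c(msg, "correlations must satisfy |rho| < 1")
  if (object@peptidesPerGene < 1)
    msg <- c(msg, "peptidesPerGene must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Construct a simulation configuration
#'
#' Builds a validated \linkS4class{SimConfig}. The defaults encode the study
#' layout the package emulates: 3 strains x 2 temperatures x 4 biological
#' replicates for transcripts, crossed with 2 technical replicate channels
#' for the labelled proteome, with channels blocked into runs so that both
#' temperatures are measured in every run (temperature never confounded with
#' run). \code{couplingRho = 0.45} puts the absolute transcript-protein
#' regression in the weak-coupling regime (r-squared near 0.2);
#' \code{fcCouplingRho = 0} makes temperature-driven transcript and protein
#' changes independent.
#'
#' @param nGenes,strains,temperatures,nBioReps,nTechReps,nRuns study layout;
#'   \code{nRuns = NULL} packs two biological-sample blocks per run.
#' @param couplingRho,fcCouplingRho,deFraction,effectSizeSd,strainEffectSd
#'   effect structure (log2 scale).
#' @param loadingOffsetSd,peptidesPerGene,peptideEffectSd,ambiguousFraction,detectProb
#'   proteomics acquisition structure.
#' @param noiseSdTranscript,noiseSdProtein,latentMean,latentSd noise and
#'   latent abundance scale (log2).
#' @param seed integer RNG seed.
#' @return A \linkS4class{SimConfig} object.
#' @examples
#' cfg <- SimConfig(nGenes = 200, seed = 7)
#' cfg
#' @export
SimConfig <- function(nGenes = 5000, strains = c("CC7", "H2", "RS"),
                      temperatures = c("control", "stress"),
                      nBioReps = 4, nTechReps = 2, nRuns = NULL,
                      couplingRho = 0.45, fcCouplingRho = 0,
                      deFraction = 0.1, effectSizeSd = 1,
                      strainEffectSd = 0, loadingOffsetSd = 0.5,
                      peptidesPerGene = 3, peptideEffectSd = 0.5,
                      ambiguousFraction = 0.10, detectProb = 0.85,
                      noiseSdTranscript = 0.25, noiseSdProtein = 0.25,
                      latentMean = 6, latentSd = 2, seed = 1) {
  if (is.null(nRuns)) {
    nBlocks <- length(strains) * nBioReps
    nRuns <- max(1L, as.integer(ceiling(nBlocks / 2)))
  }
  new("SimConfig",
      nGenes = as.integer(nGenes), strains = as.character(strains),
      temperatures = as.character(temperatures),
      nBioReps = as.integer(nBioReps), nTechReps = as.integer(nTechReps),
      nRuns = as.integer(nRuns), couplingRho = couplingRho,
      fcCouplingRho = fcCouplingRho, deFraction = deFraction,
      effectSizeSd = effectSizeSd, strainEffectSd = strainEffectSd,
      loadingOffsetSd = loadingOffsetSd, peptidesPerGene = peptidesPerGene,
      peptideEffectSd = peptideEffectSd, ambiguousFraction = ambiguousFraction,
      detectProb = detectProb, noiseSdTranscript = noiseSdTranscript,
      noiseSdProtein = noiseSdProtein, latentMean = latentMean,
      latentSd = latentSd, seed = as.integer(seed))
}

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig:", object@nGenes, "genes;",
      length(object@strains), "strain(s) x",
      length(object@temperatures), "temperature(s) x",
      object@nBioReps, "bio rep(s);",
      object@nTechReps, "tech rep(s) over", object@nRuns, "run(s)\n")
  cat(sprintf("  couplingRho = %.3g, fcCouplingRho = %.3g, deFraction = %.3g, seed = %d\n",
              object@couplingRho, object@fcCouplingRho,
              object@deFraction, object@seed))
})

#' Long-format labelled proteomics experiment
#'
#' An S4 container pairing a long peptide intensity table with its sample
#' design. The \code{stage} slot records where the table stands in the
#' normalization chain: \code{"raw"} (positive spectral intensities),
#' \code{"normalized"} (log2, per-channel median-centred), or
#' \code{"polished"} (additionally per-gene median-polished across runs).
#'
#' The peptide table has columns \code{peptide_id}, \code{gene_ids}
#' (semicolon-separated when a peptide maps ambiguously to several gene
#' models), \code{run}, \code{sample_id} and \code{intensity}; the design has
#' \code{sample_id}, \code{strain}, \code{temperature}, \code{bio_rep},
#' \code{tech_rep} and \code{run}.
#'
#' @slot peptides long-format peptide data.frame.
#' @slot design sample design data.frame (protein channels).
#' @slot stage processing stage, see above.
#' @seealso \code{\link{PeptideExperiment}},
#'   \code{\link{log2LoadingCorrect}}, \code{\link{medianPolishGenes}}
#' @export
setClass("PeptideExperiment",
  representation(peptides = "data.frame", design = "data.frame",
                 stage = "character"))

setValidity("PeptideExperiment", function(object) {
  msg <- character()
  pep <- object@peptides
  need <- c("peptide_id", "gene_ids", "run", "sample_id", "intensity")
  if (!all(need %in% colnames(pep)))
    msg <- c(msg, paste("peptide table needs columns:",
                        paste(need, collapse = ", ")))
  dneed <- c("sample_id", "strain", "temperature", "bio_rep", "tech_rep", "run")
  if (!all(dneed %in% colnames(object@design)))
    msg <- c(msg, paste("design needs columns:", paste(dneed, collapse = ", ")))
  if (!object@stage %in% c("raw", "normalized", "polished"))
    msg <- c(msg, "stage must be raw, normalized or polished")
  if (all(need %in% colnames(pep)) && nrow(pep)) {
    if (anyDuplicated(pep[, c("peptide_id", "sample_id")]))
      msg <- c(msg, "duplicate (peptide_id, sample_id) rows")
    if (identical(object@stage, "raw") && any(pep$intensity <= 0, na.rm = TRUE))
      msg <- c(msg, "raw intensities must be positive")
    if (any(!nzchar(pep$gene_ids)))
      msg <- c(msg, "every peptide needs at least one gene id")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a PeptideExperiment
#'
#' @param peptides long-format peptide table (see
#'   \linkS4class{PeptideExperiment}).
#' @param design protein-channel sample design.
#' @param stage processing stage of the intensities.
#' @return A \linkS4class{PeptideExperiment}.
#' @export
PeptideExperiment <- function(peptides, design, stage = "raw") {
  if ("assay" %in% colnames(design))
    design <- design[design$assay == "protein", , drop = FALSE]
  new("PeptideExperiment", peptides = as.data.frame(peptides),
      design = as.data.frame(design), stage = stage)
}

#' @describeIn PeptideExperiment-class number of peptide-channel observations
#' @param x,object a \code{PeptideExperiment}
#' @export
setMethod("length", "PeptideExperiment", function(x) nrow(x@peptides))

#' Accessors for PeptideExperiment
#'
#' \code{peptideData} returns the long peptide table, \code{sampleDesign} the
#' channel design, and \code{processingStage} the normalization stage.
#'
#' @param object a \linkS4class{PeptideExperiment}
#' @return data.frame or character scalar.
#' @export
setGeneric("peptideData", function(object) standardGeneric("peptideData"))

#' @rdname peptideData
#' @export
setMethod("peptideData", "PeptideExperiment", function(object) object@peptides)

#' @rdname peptideData
#' @export
setGeneric("sampleDesign", function(object) standardGeneric("sampleDesign"))

#' @rdname peptideData
#' @export
setMethod("sampleDesign", "PeptideExperiment", function(object) object@design)

#' @rdname peptideData
#' @export
setGeneric("processingStage",
           function(object) standardGeneric("processingStage"))

#' @rdname peptideData
#' @export
setMethod("processingStage", "PeptideExperiment",
          function(object) object@stage)

setMethod("show", "PeptideExperiment", function(object) {
  pep <- object@peptides
  cat("PeptideExperiment (stage:", object@stage, ")\n")
  cat(" ", length(unique(pep$peptide_id)), "peptides over",
      length(unique(pep$sample_id)), "channels in",
      length(unique(pep$run)), "run(s);", nrow(pep), "observations\n")
  amb <- grepl(";", pep$gene_ids[!duplicated(pep$peptide_id)], fixed = TRUE)
  cat(sprintf("  %.1f%% of peptides map to multiple gene models\n",
              100 * mean(amb)))
})
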