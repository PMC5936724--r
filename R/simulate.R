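# Synthetic multi-omics study generator. Every observation is
# reconstructible from the ground truth plus the recorded noise models, so
# downstream estimators can be validated against known effects.

#' Build the sample design of a simulated study
#'
#' Produces the full factorial strain x temperature x biological replicate
#' design for transcript samples, crossed with technical replicate channels
#' for the labelled proteome. Biological samples are assigned to runs in
#' whole blocks (all channels of a biological sample share a run, and both
#' temperatures of a biological replicate sit in the same run), so
#' temperature is never confounded with run.
#'
#' @param config a \linkS4class{SimConfig}.
#' @return A data.frame with columns \code{sample_id}, \code{assay}
#'   (\code{"transcript"} or \code{"protein"}), \code{strain},
#'   \code{temperature}, \code{bio_rep}, \code{tech_rep} (NA for transcript
#'   samples) and \code{run} (NA for transcript samples).
#' @examples
#' d <- simulateDesign(SimConfig(nGenes = 10))
#' table(d$assay)
#' @export
simulateDesign <- function(config) {
  stopifnot(is(config, "SimConfig"))
  validObject(config)
  g <- expand.grid(bio_rep = seq_len(config@nBioReps),
                   temperature = config@temperatures,
                   strain = config@strains,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  g <- g[, c("strain", "temperature", "bio_rep")]
  tdes <- data.frame(
    sample_id = paste(g$strain, g$temperature, paste0("b", g$bio_rep),
                      sep = "_"),
    assay = "transcript", g,
    tech_rep = NA_integer_, run = NA_character_,
    stringsAsFactors = FALSE)

  p <- merge(g, data.frame(tech_rep = seq_len(config@nTechReps)))
  p <- p[order(match(p$strain, config@strains), p$bio_rep,
               match(p$temperature, config@temperatures), p$tech_rep), ]
  # block = one biological replicate of one strain (all temps, all channels)
  blocks <- unique(p[, c("strain", "bio_rep")])
  blocks$block <- seq_len(nrow(blocks))
  perRun <- ceiling(nrow(blocks) / config@nRuns)
  blocks$run <- paste0("run", (blocks$block - 1) %/% perRun + 1)
  p <- merge(p, blocks, by = c("strain", "bio_rep"), sort = FALSE)
  pdes <- data.frame(
    sample_id = paste(p$strain, p$temperature, paste0("b", p$bio_rep),
                      paste0("t", p$tech_rep), sep = "_"),
    assay = "protein",
    strain = p$strain, temperature = p$temperature, bio_rep = p$bio_rep,
    tech_rep = p$tech_rep, run = p$run, stringsAsFactors = FALSE)
  out <- rbind(tdes, pdes)
  rownames(out) <- NULL
  out
}

#' Draw the ground truth of a simulated study
#'
#' Latent log2 transcript and protein abundances are bivariate normal with
#' correlation \code{couplingRho}. Per strain, a \code{deFraction} of genes
#' receives a temperature effect; transcript and protein effects of an
#' affected gene are bivariate normal with correlation \code{fcCouplingRho}
#' and scale \code{effectSizeSd}. Peptide counts per gene are shifted
#' Poisson (minimum 1); a fraction of peptides additionally maps to the gene
#' with the nearest latent protein abundance, making representative-gene
#' selection nontrivial. When \code{design} contains protein channels,
#' per-channel loading offsets are drawn as well.
#'
#' @param config a \linkS4class{SimConfig}.
#' @param design optional design from \code{\link{simulateDesign}}; needed
#'   for loading offsets.
#' @return A list with elements \code{genes}, \code{latentTranscript},
#'   \code{latentProtein}, \code{strainBaseTranscript},
#'   \code{strainBaseProtein}, \code{deFlag}, \code{effTranscript},
#'   \code{effProtein} (gene x strain matrices), \code{peptides} (peptide to
#'   gene map with per-peptide efficiencies) and \code{loadingOffset}
#'   (named by protein sample_id).
#' @export
simulateGroundTruth <- function(config, design = NULL) {
  stopifnot(is(config, "SimConfig"))
  n <- config@nGenes
  S <- length(config@strains)
  truth <- withSeed(config@seed, {
    genes <- sprintf("gene%05d", seq_len(n))
    latentT <- rnorm(n, config@latentMean, config@latentSd)
    z <- rnorm(n)
    rho <- config@couplingRho
    latentP <- config@latentMean + rho * (latentT - config@latentMean) +
      sqrt(1 - rho^2) * config@latentSd * z

    baseT <- matrix(rnorm(n * S, 0, config@strainEffectSd), n, S,
                    dimnames = list(genes, config@strains))
    baseP <- matrix(rnorm(n * S, 0, config@strainEffectSd), n, S,
                    dimnames = list(genes, config@strains))
    deFlag <- matrix(rbinom(n * S, 1, config@deFraction) == 1, n, S,
                     dimnames = list(genes, config@strains))
    e1 <- matrix(rnorm(n * S), n, S)
    e2 <- matrix(rnorm(n * S), n, S)
    fr <- config@fcCouplingRho
    effT <- config@effectSizeSd * e1
    effP <- config@effectSizeSd * (fr * e1 + sqrt(1 - fr^2) * e2)
    effT[!deFlag] <- 0
    effP[!deFlag] <- 0
    dimnames(effT) <- dimnames(effP) <- list(genes, config@strains)

    k <- 1L + rpois(n, config@peptidesPerGene - 1)
    geneOfPep <- rep(seq_len(n), k)
    P <- length(geneOfPep)
    amb <- runif(P) < config@ambiguousFraction
    # ambiguous partner: gene with the nearest latent protein abundance
    ord <- order(latentP)
    pos <- match(seq_len(n), ord)
    nearest <- function(i) {
      p <- pos[i]
      lo <- if (p > 1) ord[p - 1] else NA_integer_
      hi <- if (p < n) ord[p + 1] else NA_integer_
      if (is.na(lo)) return(hi)
      if (is.na(hi)) return(lo)
      if (abs(latentP[lo] - latentP[i]) <= abs(latentP[hi] - latentP[i])) lo
      else hi
    }
    gidStr <- genes[geneOfPep]
    if (n > 1 && any(amb)) {
      partner <- vapply(geneOfPep[amb], nearest, integer(1))
      pair <- cbind(genes[geneOfPep[amb]], genes[partner])
      gidStr[amb] <- apply(pair, 1, function(x) paste(sort(x), collapse = ";"))
    }
    peptides <- data.frame(
      peptide_id = sprintf("pep%06d", seq_len(P)),
      gene_id = genes[geneOfPep],
      gene_ids = gidStr,
      efficiency = rnorm(P, 0, config@peptideEffectSd),
      stringsAsFactors = FALSE)
    list(genes = genes, latentTranscript = latentT, latentProtein = latentP,
         strainBaseTranscript = baseT, strainBaseProtein = baseP,
         deFlag = deFlag, effTranscript = effT, effProtein = effP,
         peptides = peptides)
  })
  if (!is.null(design)) {
    pdes <- design[design$assay == "protein", , drop = FALSE]
    if (nrow(pdes)) {
      truth$loadingOffset <- withSeed(config@seed + 2L,
        setNames(rnorm(nrow(pdes), 0, config@loadingOffsetSd),
                 pdes$sample_id))
    }
  }
  truth
}

#' Simulate a transcript abundance (TPM) matrix
#'
#' Log2 latent abundances receive per-strain baselines, temperature effects
#' on stress samples of affected genes, and Gaussian noise; the linear-scale
#' matrix is then column-rescaled so each sample sums to one million
#' (transcripts per million).
#'
#' @param config a \linkS4class{SimConfig}.
#' @param design design from \code{\link{simulateDesign}}.
#' @param truth ground truth from \code{\link{simulateGroundTruth}}.
#' @return genes x transcript-samples numeric matrix of TPM values.
#' @export
simulateTranscriptome <- function(config, design, truth) {
  tdes <- design[design$assay == "transcript", , drop = FALSE]
  n <- config@nGenes
  withSeed(config@seed + 1L, {
    m <- matrix(0, n, nrow(tdes),
                dimnames = list(truth$genes, tdes$sample_id))
    for (j in seq_len(nrow(tdes))) {
      s <- tdes$strain[j]
      lv <- truth$latentTranscript + truth$strainBaseTranscript[, s] +
        (tdes$temperature[j] == "stress") * truth$effTranscript[, s] +
        rnorm(n, 0, config@noiseSdTranscript)
      m[, j] <- 2^lv
    }
    sweep(m, 2, colSums(m), "/") * 1e6
  })
}

#' Simulate a labelled-proteomics peptide table
#'
#' Per peptide and channel, the log2 intensity is the latent protein
#' abundance of the parent gene plus its strain baseline, the temperature
#' effect on stress channels, the channel's loading offset, the peptide's
#' detection efficiency, and Gaussian noise; the linear-scale intensity is
#' \code{2^value}. Observations are then thinned by the per-channel
#' detection probability.
#'
#' @inheritParams simulateTranscriptome
#' @return A \linkS4class{PeptideExperiment} at stage \code{"raw"}.
#' @export
simulateProteome <- function(config, design, truth) {
  pdes <- design[design$assay == "protein", , drop = FALSE]
  if (!nrow(pdes)) stop("design contains no protein channels")
  if (is.null(truth$loadingOffset))
    truth$loadingOffset <- setNames(rep(0, nrow(pdes)), pdes$sample_id)
  pm <- truth$peptides
  P <- nrow(pm)
  C <- nrow(pdes)
  gi <- match(pm$gene_id, truth$genes)
  si <- match(pdes$strain, config@strains)
  stress <- pdes$temperature == "stress"
  off <- truth$loadingOffset[pdes$sample_id]
  long <- withSeed(config@seed + 3L, {
    pep <- rep(seq_len(P), times = C)
    ch <- rep(seq_len(C), each = P)
    val <- truth$latentProtein[gi[pep]] +
      truth$strainBaseProtein[cbind(gi[pep], si[ch])] +
      stress[ch] * truth$effProtein[cbind(gi[pep], si[ch])] +
      off[ch] + pm$efficiency[pep] +
      rnorm(P * C, 0, config@noiseSdProtein)
    keep <- runif(P * C) < config@detectProb
    data.frame(peptide_id = pm$peptide_id[pep[keep]],
               gene_ids = pm$gene_ids[pep[keep]],
               run = pdes$run[ch[keep]],
               sample_id = pdes$sample_id[ch[keep]],
               intensity = 2^val[keep],
               stringsAsFactors = FALSE)
  })
  PeptideExperiment(long, pdes, stage = "raw")
}

#' Simulate a complete synthetic study
#'
#' Convenience wrapper drawing design, ground truth, TPM matrix and peptide
#' table in one call. Identical configuration (including seed) yields
#' byte-identical results.
#'
#' @param config a \linkS4class{SimConfig}.
#' @return A list with elements \code{config}, \code{design}, \code{truth},
#'   \code{tpm} and \code{peptides}.
#' @examples
#' study <- simulateStudy(SimConfig(nGenes = 50, seed = 3))
#' dim(study$tpm)
#' @export
simulateStudy <- function(config) {
  design <- simulateDesign(config)
  truth <- simulateGroundTruth(config, design)
  tpm <- simulateTranscriptome(config, design, truth)
  peptides <- simulateProteome(config, design, truth)
  list(config = config, design = design, truth = truth,
       tpm = tpm, peptides = peptides)
}

#' Simulate a synthetic ROS assay table
#'
#' Generates a small reactive-oxygen-species fluorescence and cell-count
#' table for in-host and isolated-symbiont measurements. This is a synthetic
#' stand-in for a plate-reader export: per strain, stress multiplies the
#' per-cell fluorescence by a strain-specific factor (damped in the
#' heat-adapted strain by default), in-host signal sits below the isolate
#' signal, and both fluorescence and cell counts carry log-normal noise.
#'
#' @param strains strain labels.
#' @param nReps biological replicates per strain, temperature and context.
#' @param baseline per-cell fluorescence at control, per strain (recycled).
#' @param stressFactor multiplicative stress response per strain (recycled).
#' @param hostAttenuation factor applied to in-host signal relative to
#'   isolates.
#' @param cv log-normal coefficient of variation of fluorescence per cell.
#' @param meanCells mean symbiont cell count per sample.
#' @param seed integer RNG seed.
#' @return data.frame with columns \code{strain}, \code{temperature},
#'   \code{context}, \code{replicate}, \code{fluorescence},
#'   \code{cell_count}.
#' @export
simulateRos <- function(strains = c("CC7", "H2", "RS"), nReps = 4,
                        baseline = 2, stressFactor = c(1.8, 1.7, 1.15),
                        hostAttenuation = 0.6, cv = 0.15,
                        meanCells = 5e4, seed = 1) {
  baseline <- rep_len(baseline, length(strains))
  stressFactor <- rep_len(stressFactor, length(strains))
  g <- expand.grid(replicate = seq_len(nReps),
                   temperature = c("control", "stress"),
                   context = c("in_hospite", "isolate"),
                   strain = strains,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  withSeed(seed, {
    i <- match(g$strain, strains)
    perCell <- baseline[i] *
      ifelse(g$temperature == "stress", stressFactor[i], 1) *
      ifelse(g$context == "in_hospite", hostAttenuation, 1) *
      exp(rnorm(nrow(g), 0, cv))
    cells <- round(meanCells * exp(rnorm(nrow(g), 0, 0.2)))
    data.frame(g[, c("strain", "temperature", "context", "replicate")],
               fluorescence = perCell * cells, cell_count = cells,
               stringsAsFactors = FALSE)
  })
}
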