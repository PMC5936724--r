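# Reference-standard-free normalization of labelled proteomics data:
# per-channel loading correction followed by per-gene median polish across
# runs, then detection filtering and gene-level summarization. Because both
# corrections are medians of the data themselves, no reference channel is
# needed, and relative expression is comparable within and across runs.

#' Log2-transform and correct for loading effects
#'
#' Spectral intensities are log2-transformed, then for every channel
#' (\code{sample_id} within a run) the median log2 intensity over all its
#' peptides is subtracted. This removes the loading effect: the per-channel
#' shift in absolute signal caused by differing amounts of input material.
#' After correction every channel has median 0.
#'
#' @param pe a \linkS4class{PeptideExperiment} at stage \code{"raw"}.
#' @return A \linkS4class{PeptideExperiment} at stage \code{"normalized"};
#'   the \code{intensity} column now holds centred log2 values.
#' @examples
#' study <- simulateStudy(SimConfig(nGenes = 30, seed = 1))
#' norm <- log2LoadingCorrect(study$peptides)
#' processingStage(norm)
#' @export
log2LoadingCorrect <- function(pe) {
  stopifnot(is(pe, "PeptideExperiment"))
  if (pe@stage != "raw")
    stop("log2LoadingCorrect expects raw intensities (stage 'raw'), got '",
         pe@stage, "'")
  pep <- pe@peptides
  bad <- which(!is.finite(pep$intensity) | pep$intensity <= 0)
  if (length(bad))
    stop("nonpositive or non-finite intensity for peptide '",
         pep$peptide_id[bad[1]], "' in channel '", pep$sample_id[bad[1]],
         "' (row ", bad[1], ")")
  des <- pe@design
  empty <- setdiff(des$sample_id, unique(pep$sample_id))
  if (length(empty)) {
    warning("dropping channel(s) with no detected peptides: ",
            paste(empty, collapse = ", "))
    des <- des[!des$sample_id %in% empty, , drop = FALSE]
  }
  x <- as.data.table(pep)
  x[, intensity := log2(intensity)]
  x[, intensity := intensity - median(intensity), by = sample_id]
  new("PeptideExperiment", peptides = as.data.frame(x), design = des,
      stage = "normalized")
}

#' Re-centre channels at median zero
#'
#' The centring half of \code{\link{log2LoadingCorrect}}, applicable to
#' already-log2 data. Idempotent: channels at median 0 are unchanged.
#'
#' @param pe a \linkS4class{PeptideExperiment} at stage \code{"normalized"}
#'   or \code{"polished"}.
#' @return The experiment with every channel median-centred at 0.
#' @export
loadingCorrect <- function(pe) {
  stopifnot(is(pe, "PeptideExperiment"))
  if (pe@stage == "raw")
    stop("loadingCorrect operates on log2 data; use log2LoadingCorrect first")
  x <- as.data.table(pe@peptides)
  x[, intensity := intensity - median(intensity), by = sample_id]
  initialize(pe, peptides = as.data.frame(x))
}

#' Median-polish log2 intensities per gene across runs
#'
#' For each gene (peptides with an ambiguous mapping are polished as their
#' own multi-gene group), the gene's values within each run are summarized
#' by their median; the median of these run summaries across runs is then
#' subtracted from all the gene's values. Afterwards every gene's cross-run
#' median of run summaries is 0, making relative expression of the same
#' protein comparable across runs. A single polish pass is performed per
#' axis (channels, then genes), not an iterated Tukey polish.
#'
#' @param pe a loading-corrected \linkS4class{PeptideExperiment} (stage
#'   \code{"normalized"} or \code{"polished"}; the operation is idempotent).
#' @return A \linkS4class{PeptideExperiment} at stage \code{"polished"}.
#' @export
medianPolishGenes <- function(pe) {
  stopifnot(is(pe, "PeptideExperiment"))
  if (pe@stage == "raw")
    stop("medianPolishGenes expects loading-corrected log2 data")
  x <- as.data.table(pe@peptides)
  runSummary <- x[, .(s = median(intensity)), by = .(gene_ids, run)]
  offset <- runSummary[, .(off = median(s)), by = gene_ids]
  x <- offset[x, on = "gene_ids"]
  x[, intensity := intensity - off]
  x[, off := NULL]
  setcolorder(x, colnames(pe@peptides))
  new("PeptideExperiment", peptides = as.data.frame(x), design = pe@design,
      stage = "polished")
}

#' Filter rarely detected peptides per strain-temperature group
#'
#' Within each strain x temperature group, a peptide is retained only if it
#' was detected in at least \code{minTech} technical replicate channels and
#' at least \code{minBio} biological replicates. The decision is made per
#' group: a peptide may survive in one strain-temperature combination and be
#' dropped in another. Under the default reading, the technical-replicate
#' count pools channels across biological replicates; \code{strict = TRUE}
#' instead requires some single biological replicate to contribute
#' \code{minTech} channels.
#'
#' @param pe a \linkS4class{PeptideExperiment} (any stage).
#' @param minTech minimum technical replicate channels per group.
#' @param minBio minimum biological replicates per group.
#' @param strict require \code{minTech} channels within one biological
#'   replicate.
#' @return The experiment with failing peptide-group observations removed.
#' @export
filterDetection <- function(pe, minTech = 2, minBio = 1, strict = FALSE) {
  stopifnot(is(pe, "PeptideExperiment"))
  x <- as.data.table(pe@peptides)
  des <- as.data.table(pe@design)[, .(sample_id, strain, temperature, bio_rep)]
  missing <- setdiff(unique(x$sample_id), des$sample_id)
  if (length(missing))
    stop("sample_id(s) absent from design: ", paste(missing, collapse = ", "))
  x <- des[x, on = "sample_id"]
  perBio <- x[, .(nt = uniqueN(sample_id)),
              by = .(peptide_id, strain, temperature, bio_rep)]
  det <- perBio[, .(ntech = sum(nt), nbio = .N, maxWithin = max(nt)),
                by = .(peptide_id, strain, temperature)]
  det[, keep := ntech >= minTech & nbio >= minBio]
  if (strict) det[, keep := keep & maxWithin >= minTech]
  x <- det[, .(peptide_id, strain, temperature, keep)][
    x, on = c("peptide_id", "strain", "temperature")]
  x <- x[keep == TRUE]
  x <- x[, colnames(pe@peptides), with = FALSE]
  initialize(pe, peptides = as.data.frame(x))
}

#' Summarize relative protein expression per strain-temperature group
#'
#' Computes, for every gene and strain-temperature combination, the mean of
#' all surviving peptide-channel log2 values (the relative expression), its
#' standard error (sample standard deviation over the square root of the
#' number of values; 0 when only one value is present), and the number of
#' technical channels and biological replicates the gene was detected in.
#' Peptides mapping to multiple gene models are excluded here by default,
#' after having participated in normalization.
#'
#' @param pe a filtered, polished \linkS4class{PeptideExperiment}.
#' @param dropAmbiguous exclude multi-gene peptides from summarization.
#' @return data.frame with columns \code{gene_id}, \code{strain},
#'   \code{temperature}, \code{mean_log2}, \code{se_log2}, \code{n_tech},
#'   \code{n_bio}.
#' @export
summarizeRelExpr <- function(pe, dropAmbiguous = TRUE) {
  stopifnot(is(pe, "PeptideExperiment"))
  if (pe@stage != "polished")
    warning("summarizing values at stage '", pe@stage,
            "'; expected median-polished data")
  x <- as.data.table(pe@peptides)
  if (dropAmbiguous) x <- x[!grepl(";", gene_ids, fixed = TRUE)]
  des <- as.data.table(pe@design)[, .(sample_id, strain, temperature, bio_rep)]
  x <- des[x, on = "sample_id"]
  out <- x[, .(mean_log2 = mean(intensity),
               se_log2 = if (.N > 1) sd(intensity) / sqrt(.N) else 0,
               n_tech = uniqueN(sample_id),
               n_bio = uniqueN(bio_rep)),
           by = .(gene_id = gene_ids, strain, temperature)]
  setorder(out, gene_id, strain, temperature)
  as.data.frame(out)
}

#' Per-channel gene-level values of a polished experiment
#'
#' Averages the polished log2 values of each gene's peptides within every
#' channel, giving the replicate-level matrix used by the protein t-test and
#' the two-factor linear model.
#'
#' @inheritParams summarizeRelExpr
#' @return genes x channels numeric matrix (NA where a gene was not
#'   detected in a channel), with the channel design attached as attribute
#'   \code{"design"}.
#' @export
proteinChannelMatrix <- function(pe, dropAmbiguous = TRUE) {
  stopifnot(is(pe, "PeptideExperiment"))
  x <- as.data.table(pe@peptides)
  if (dropAmbiguous) x <- x[!grepl(";", gene_ids, fixed = TRUE)]
  agg <- x[, .(value = mean(intensity)), by = .(gene_ids, sample_id)]
  wide <- dcast(agg, gene_ids ~ sample_id, value.var = "value")
  m <- as.matrix(wide[, -1])
  rownames(m) <- wide$gene_ids
  des <- pe@design
  m <- m[, intersect(des$sample_id, colnames(m)), drop = FALSE]
  attr(m, "design") <- des[match(colnames(m), des$sample_id), , drop = FALSE]
  m
}
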