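# Transcriptome-proteome integration: shared abundance units (TPM / SCPM),
# ambiguity handling, longest-isoform reduction, absolute and fold-change
# regressions, and concordance classification of differentially expressed
# proteins against their transcripts.

#' Keep the longest isoform per locus
#'
#' Reduces an isoform table to exactly one isoform per locus — the longest,
#' ties broken deterministically by the lexicographically smallest isoform
#' id — mirroring the reduction used to shrink a gene-model catalogue before
#' read mapping.
#'
#' @param isoforms data.frame with columns \code{locus}, \code{isoform_id},
#'   \code{length}.
#' @return data.frame of kept rows, one per locus, ordered by locus.
#' @export
reduceLongestIsoform <- function(isoforms) {
  .checkCols(isoforms, c("locus", "isoform_id", "length"), "isoform table")
  if (anyDuplicated(isoforms$isoform_id))
    stop("duplicate isoform id(s): ",
         paste(unique(isoforms$isoform_id[duplicated(isoforms$isoform_id)]),
               collapse = ", "))
  if (any(isoforms$length <= 0)) stop("isoform lengths must be positive")
  x <- isoforms[order(isoforms$locus, -isoforms$length, isoforms$isoform_id), ]
  out <- x[!duplicated(x$locus), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Spectral counts per million
#'
#' Rescales each column of a nonnegative gene x sample count matrix to sum
#' to one million, the protein-side analogue of TPM.
#'
#' @param counts nonnegative genes x samples matrix.
#' @return Matrix of the same shape with columns summing to 1e6.
#' @export
computeScpm <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0, na.rm = TRUE)) stop("counts must be nonnegative")
  tot <- colSums(counts, na.rm = TRUE)
  if (any(tot == 0))
    stop("all-zero column(s): ",
         paste(colnames(counts)[tot == 0], collapse = ", "))
  sweep(counts, 2, tot, "/") * 1e6
}

#' Remove ambiguously mapped peptides
#'
#' Drops every peptide that could originate from more than one gene model,
#' reporting the removed fraction (of unique peptides) as attribute
#' \code{"report"}. With the simulator's defaults about 10\% of peptides
#' are ambiguous.
#'
#' @param pe a \linkS4class{PeptideExperiment}.
#' @return The experiment restricted to single-gene peptides.
#' @export
dropAmbiguousPeptides <- function(pe) {
  stopifnot(is(pe, "PeptideExperiment"))
  pep <- pe@peptides
  ambRow <- grepl(";", pep$gene_ids, fixed = TRUE)
  uniq <- !duplicated(pep$peptide_id)
  frac <- if (any(uniq)) mean(ambRow[uniq]) else 0
  out <- initialize(pe, peptides = pep[!ambRow, , drop = FALSE])
  if (nrow(out@peptides) == 0 && nrow(pep) > 0)
    warning("all peptides were ambiguous; empty experiment returned")
  attr(out, "report") <- list(
    n_peptides = sum(uniq), n_removed = sum(ambRow & uniq),
    fraction_removed = frac)
  out
}

#' Choose a representative gene model per ambiguous peptide
#'
#' For each semicolon-separated candidate set, picks the candidate with the
#' highest mean transcript abundance across samples; ties (and candidate
#' sets entirely absent from the TPM matrix) fall back to the
#' lexicographically smallest id, the latter with a warning. Used before
#' functional enrichment so that each peptide contributes at most one gene,
#' avoiding over-representation of functional categories shared by all of a
#' peptide's candidate genes.
#'
#' @param geneIds character vector; each element one gene id or several
#'   separated by \code{";"}.
#' @param tpm genes x samples TPM matrix.
#' @return character vector of single representative gene ids.
#' @export
chooseRepresentative <- function(geneIds, tpm) {
  meanTpm <- rowMeans(tpm)
  fellBack <- FALSE
  out <- vapply(strsplit(as.character(geneIds), ";", fixed = TRUE),
    function(cand) {
      cand <- sort(cand)
      if (length(cand) == 1) return(cand)
      mt <- meanTpm[cand]
      if (all(is.na(mt))) { fellBack <<- TRUE; return(cand[1]) }
      mt[is.na(mt)] <- -Inf
      cand[which.max(mt)]  # first max = lexicographically smallest on ties
    }, character(1))
  if (fellBack)
    warning("candidate set(s) absent from the TPM matrix; ",
            "fell back to lexicographic choice")
  out
}

#' Protein abundance matrix on the transcript sample grid
#'
#' Builds per-biological-replicate protein abundances comparable to TPM
#' columns: raw peptide intensities (single-gene peptides only, by default)
#' are summed per gene within each channel, each channel is rescaled to
#' spectral counts per million, and channels of the same biological
#' replicate are averaged. Columns are named like the matching transcript
#' samples (\code{strain_temperature_bN}).
#'
#' @param pe a \emph{raw} \linkS4class{PeptideExperiment}.
#' @param dropAmbiguous exclude multi-gene peptides.
#' @return genes x biological-replicate SCPM matrix (0 = not detected).
#' @export
proteinScpm <- function(pe, dropAmbiguous = TRUE) {
  stopifnot(is(pe, "PeptideExperiment"))
  if (pe@stage != "raw")
    stop("proteinScpm needs raw intensities (absolute abundance)")
  x <- as.data.table(pe@peptides)
  if (dropAmbiguous) x <- x[!grepl(";", gene_ids, fixed = TRUE)]
  agg <- x[, .(total = sum(intensity)), by = .(gene_ids, sample_id)]
  wide <- dcast(agg, gene_ids ~ sample_id, value.var = "total", fill = 0)
  m <- as.matrix(wide[, -1])
  rownames(m) <- wide$gene_ids
  scpm <- computeScpm(m)
  des <- pe@design[match(colnames(scpm), pe@design$sample_id), ]
  grp <- paste(des$strain, des$temperature, paste0("b", des$bio_rep),
               sep = "_")
  cols <- unique(grp)
  out <- vapply(cols, function(g)
    rowMeans(scpm[, grp == g, drop = FALSE]), numeric(nrow(scpm)))
  colnames(out) <- cols
  out
}

.regress <- function(xv, yv, label) {
  ok <- is.finite(xv) & is.finite(yv)
  xv <- xv[ok]; yv <- yv[ok]
  if (length(xv) < 3)
    stop("fewer than 3 points for regression '", label, "'")
  fit <- lm(yv ~ xv)
  sm <- summary(fit)
  data.frame(label = label,
             slope = unname(coef(fit)[2]),
             intercept = unname(coef(fit)[1]),
             r2 = sm$r.squared,
             p = unname(sm$coefficients[2, 4]),
             n_points = length(xv),
             stringsAsFactors = FALSE)
}

#' Absolute transcript-protein regression
#'
#' Ordinary least squares of log2(SCPM + pseudocount) on
#' log2(TPM + pseudocount) over pooled (gene, biological replicate) points
#' of one strain and temperature. Only points where the gene was detected
#' in both data sets enter. In the simulator's no-noise limit the expected
#' r-squared equals the squared latent coupling correlation.
#'
#' @param tpm genes x transcript-samples TPM matrix.
#' @param scpm genes x biological-replicate SCPM matrix from
#'   \code{\link{proteinScpm}} (columns named like transcript samples).
#' @param design design table.
#' @param strain,temperature the group to regress.
#' @param pseudocount added before log2.
#' @param perReplicate if TRUE, return one regression row per biological
#'   replicate instead of pooling.
#' @return RegressionResult data.frame: \code{label}, \code{slope},
#'   \code{intercept}, \code{r2}, \code{p}, \code{n_points}.
#' @export
absoluteCorrelation <- function(tpm, scpm, design, strain, temperature,
                                pseudocount = 1, perReplicate = FALSE) {
  des <- design[design$assay == "transcript" & design$strain == strain &
                design$temperature == temperature, , drop = FALSE]
  ids <- intersect(des$sample_id, colnames(scpm))
  if (!length(ids)) stop("no matching replicate columns between TPM and SCPM")
  genes <- intersect(rownames(tpm), rownames(scpm))
  collect <- function(id) {
    t <- tpm[genes, id]
    p <- scpm[genes, id]
    keep <- t > 0 & p > 0
    cbind(log2(t[keep] + pseudocount), log2(p[keep] + pseudocount))
  }
  if (perReplicate) {
    do.call(rbind, lapply(ids, function(id) {
      pts <- collect(id)
      .regress(pts[, 1], pts[, 2], paste(strain, temperature, id, sep = ":"))
    }))
  } else {
    pts <- do.call(rbind, lapply(ids, collect))
    .regress(pts[, 1], pts[, 2], paste(strain, temperature, sep = ":"))
  }
}

#' Fold-change regression between transcript and protein responses
#'
#' Ordinary least squares of protein log2 fold changes on transcript log2
#' fold changes over the genes present in both tables, optionally
#' restricted to proteins called differentially expressed (mirroring the
#' check that removing non-significant proteins does not rescue the
#' correlation).
#'
#' @param det transcript DERecord table.
#' @param dep protein DERecord table (same contrast orientation).
#' @param restrictSignificant use only rows of \code{dep} with
#'   \code{significant == TRUE}.
#' @param label label for the regression row.
#' @return RegressionResult data.frame (one row).
#' @export
foldchangeCorrelation <- function(det, dep, restrictSignificant = FALSE,
                                  label = NULL) {
  if (restrictSignificant) dep <- dep[dep$significant, , drop = FALSE]
  shared <- intersect(det$gene_id, dep$gene_id)
  if (length(shared) < 3) stop("fewer than 3 shared genes")
  if (is.null(label))
    label <- paste(unique(dep$contrast)[1],
                   if (restrictSignificant) "(significant proteins)" else "",
                   sep = " ")
  .regress(det$log2fc[match(shared, det$gene_id)],
           dep$log2fc[match(shared, dep$gene_id)], trimws(label))
}

#' Classify transcript-protein concordance of differential proteins
#'
#' Each differentially expressed protein is classified against its
#' transcript: \code{concordant} when the transcript is significantly
#' changed in the same direction, \code{discordant} when significantly
#' changed in the opposite direction, and \code{protein_only} when the
#' transcript shows no significant change (or was not tested). The summary
#' attribute reports class counts and the percentage of concordant changes
#' among all differentially expressed proteins.
#'
#' @param dep protein DERecord table (the fold-change caller's output).
#' @param det transcript DERecord table for the same contrast.
#' @return data.frame with \code{gene_id}, \code{contrast},
#'   \code{protein_dir}, \code{transcript_dir}, \code{class}; attribute
#'   \code{"summary"} holds the counts and \code{concordant_pct}.
#' @export
classifyConcordance <- function(dep, det) {
  sig <- dep[dep$significant, , drop = FALSE]
  tdir <- det$direction[match(sig$gene_id, det$gene_id)]
  tdir[is.na(tdir)] <- "none"
  pdir <- ifelse(sig$log2fc > 0, "up", "down")
  class <- ifelse(tdir == "none", "protein_only",
                  ifelse(tdir == pdir, "concordant", "discordant"))
  out <- data.frame(gene_id = sig$gene_id, contrast = sig$contrast,
                    protein_dir = pdir, transcript_dir = tdir,
                    class = class, stringsAsFactors = FALSE)
  n <- nrow(out)
  attr(out, "summary") <- list(
    n_dep = n,
    concordant = sum(class == "concordant"),
    discordant = sum(class == "discordant"),
    protein_only = sum(class == "protein_only"),
    concordant_pct = if (n) 100 * sum(class == "concordant") / n else NA_real_)
  out
}
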