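# Differential expression callers. Transcripts are tested with a Welch
# t-test on log2(TPM + 1) — a documented proxy for bootstrap-based
# abundance-aware engines, kept at the same Benjamini-Hochberg q < 0.05
# threshold. Proteins are called primarily by a permissive 1.2-fold rule on
# median-polished relative expressions, with Welch t-tests and a two-factor
# linear model reported alongside (not intersected).

#' Benjamini-Hochberg step-up adjustment
#'
#' Thin wrapper around \code{stats::p.adjust(method = "BH")} with the
#' convention that missing p-values are propagated as missing and excluded
#' from the number of tests \code{m}.
#'
#' @param p numeric vector of p-values in [0, 1] (NA/NaN allowed).
#' @return Vector of BH-adjusted q-values, same length and order.
#' @examples
#' bhAdjust(c(0.01, 0.02, 0.04))
#' @export
bhAdjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  q <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  q[ok] <- p.adjust(p[ok], method = "BH")
  q
}

# Shared machinery: Welch test of B vs A column sets on a log2-scale matrix.
.welchDe <- function(logm, colsA, colsB, contrast, alpha) {
  w <- rowWelch(logm[, colsA, drop = FALSE], logm[, colsB, drop = FALSE])
  q <- bhAdjust(w$p)
  .deRecord(rownames(logm), contrast, w$meanB - w$meanA, w$stat, w$p, q, alpha)
}

#' Transcript differential expression under heat stress
#'
#' Welch t-test per gene on log2(TPM + pseudocount), stress versus control
#' within one strain, Benjamini-Hochberg corrected across the genes with
#' detectable expression in that strain. The log2 fold change is the stress
#' minus control difference of mean log2 abundances.
#'
#' @param tpm genes x samples TPM matrix (transcript sample ids as columns).
#' @param design design table (see \code{\link{simulateDesign}}).
#' @param strain strain label to test.
#' @param alpha significance threshold on the adjusted p-value.
#' @param pseudocount added to TPM before log2.
#' @return A DERecord data.frame: \code{gene_id}, \code{contrast},
#'   \code{log2fc}, \code{stat}, \code{p}, \code{q}, \code{significant},
#'   \code{direction}.
#' @export
transcriptDe <- function(tpm, design, strain, alpha = 0.05, pseudocount = 1) {
  des <- design[design$assay == "transcript" & design$strain == strain, ,
                drop = FALSE]
  ctl <- des$sample_id[des$temperature == "control"]
  str <- des$sample_id[des$temperature == "stress"]
  if (length(ctl) < 2 || length(str) < 2)
    stop("need >= 2 replicates per condition for strain ", strain)
  m <- tpm[, c(ctl, str), drop = FALSE]
  m <- m[rowSums(m) > 0, , drop = FALSE]
  logm <- log2(m + pseudocount)
  .welchDe(logm, ctl, str,
           sprintf("%s:stress-vs-control", strain), alpha)
}

#' Fold-change rule for differentially expressed proteins
#'
#' The primary protein caller: a gene is differentially expressed in a
#' strain when the absolute log2 fold change between mean relative
#' expression at stress and at control reaches \code{log2(fcThreshold)}
#' (boundary inclusive). No p-value is attached; this is a rule-based call
#' with a deliberately permissive default threshold of 1.2-fold in either
#' direction. Genes quantified in only one temperature are excluded and
#' counted in the \code{"excluded"} attribute.
#'
#' @param relexpr output of \code{\link{summarizeRelExpr}}.
#' @param strain strain label.
#' @param fcThreshold linear-scale fold-change threshold.
#' @return DERecord data.frame (with \code{p} and \code{q} NA); attribute
#'   \code{"excluded"} holds the genes seen in one temperature only.
#' @export
proteinFcDe <- function(relexpr, strain, fcThreshold = 1.2) {
  r <- relexpr[relexpr$strain == strain, , drop = FALSE]
  ctl <- r[r$temperature == "control", c("gene_id", "mean_log2")]
  str <- r[r$temperature == "stress", c("gene_id", "mean_log2")]
  shared <- intersect(ctl$gene_id, str$gene_id)
  excluded <- setdiff(union(ctl$gene_id, str$gene_id), shared)
  fc <- str$mean_log2[match(shared, str$gene_id)] -
    ctl$mean_log2[match(shared, ctl$gene_id)]
  cut <- log2(fcThreshold)
  significant <- abs(fc) >= cut
  out <- data.frame(gene_id = shared,
                    contrast = sprintf("%s:stress-vs-control", strain),
                    log2fc = fc, stat = NA_real_, p = NA_real_, q = NA_real_,
                    significant = significant,
                    direction = ifelse(!significant | fc == 0, "none",
                                       ifelse(fc > 0, "up", "down")),
                    stringsAsFactors = FALSE)
  attr(out, "excluded") <- excluded
  out
}

#' Welch t-tests on per-channel protein values
#'
#' Tests, per gene, the polished per-channel values at stress versus control
#' within one strain; Benjamini-Hochberg correction is applied over the
#' tested set (the detection-filtered protein universe of that strain).
#' Genes with fewer than two values in either temperature are skipped and
#' listed in the \code{"skipped"} attribute.
#'
#' @param channelMat genes x channels matrix from
#'   \code{\link{proteinChannelMatrix}}.
#' @param design protein-channel design (taken from the matrix's
#'   \code{"design"} attribute when NULL).
#' @param strain strain label.
#' @param alpha significance threshold on the adjusted p-value.
#' @return DERecord data.frame with attribute \code{"skipped"}.
#' @export
proteinTtest <- function(channelMat, design = NULL, strain, alpha = 0.05) {
  if (is.null(design)) design <- attr(channelMat, "design")
  des <- design[design$strain == strain, , drop = FALSE]
  ctl <- intersect(des$sample_id[des$temperature == "control"],
                   colnames(channelMat))
  str <- intersect(des$sample_id[des$temperature == "stress"],
                   colnames(channelMat))
  w <- rowWelch(channelMat[, ctl, drop = FALSE],
                channelMat[, str, drop = FALSE])
  tested <- w$tested
  out <- .deRecord(rownames(channelMat)[tested],
                   sprintf("%s:stress-vs-control", strain),
                   (w$meanB - w$meanA)[tested], w$stat[tested], w$p[tested],
                   bhAdjust(w$p[tested]), alpha)
  attr(out, "skipped") <- rownames(channelMat)[!tested]
  out
}

#' Two-factor linear model per protein
#'
#' Fits, per gene, a Gaussian linear model of polished per-channel values on
#' strain, temperature and their interaction, and extracts partial F-test
#' p-values per term (type II: each main effect against the additive model,
#' the interaction against the full model). Benjamini-Hochberg correction is
#' applied per term across genes. Genes without at least two strains
#' crossed with both temperatures (or with a rank-deficient fit) get NA
#' p-values and are flagged in the \code{"degenerate"} attribute.
#'
#' @inheritParams proteinTtest
#' @return GLMRecord data.frame: \code{gene_id}, \code{p_strain},
#'   \code{p_temperature}, \code{p_interaction} and the per-term BH
#'   \code{q_*} columns.
#' @export
proteinGlm <- function(channelMat, design = NULL, alpha = 0.05) {
  if (is.null(design)) design <- attr(channelMat, "design")
  des <- design[match(colnames(channelMat), design$sample_id), , drop = FALSE]
  strainF <- factor(des$strain)
  tempF <- factor(des$temperature)
  fitGene <- function(y) {
    ok <- !is.na(y)
    d <- data.frame(y = y[ok], strain = droplevels(strainF[ok]),
                    temperature = droplevels(tempF[ok]))
    tab <- table(d$strain, d$temperature)
    if (nlevels(d$temperature) < 2 || sum(rowSums(tab > 0) == 2) < 2)
      return(c(NA_real_, NA_real_, NA_real_))
    res <- tryCatch({
      fitF <- lm(y ~ strain * temperature, data = d)
      fitA <- lm(y ~ strain + temperature, data = d)
      fitS <- lm(y ~ strain, data = d)
      fitT <- lm(y ~ temperature, data = d)
      c(anova(fitT, fitA)[2, "Pr(>F)"],
        anova(fitS, fitA)[2, "Pr(>F)"],
        anova(fitA, fitF)[2, "Pr(>F)"])
    }, error = function(e) c(NA_real_, NA_real_, NA_real_))
    as.numeric(res)
  }
  ps <- t(apply(channelMat, 1, fitGene))
  out <- data.frame(gene_id = rownames(channelMat),
                    p_strain = ps[, 1], p_temperature = ps[, 2],
                    p_interaction = ps[, 3],
                    q_strain = bhAdjust(ps[, 1]),
                    q_temperature = bhAdjust(ps[, 2]),
                    q_interaction = bhAdjust(ps[, 3]),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "degenerate") <- out$gene_id[is.na(out$p_temperature)]
  out
}

#' Transcript contrast between two strains at fixed temperature
#'
#' Same Welch-on-log2(TPM + 1) machinery as \code{\link{transcriptDe}}, with
#' the groups being two strains measured at the same temperature. The log2
#' fold change is strainY minus strainX.
#'
#' @inheritParams transcriptDe
#' @param temperature \code{"control"} or \code{"stress"}.
#' @param strainX,strainY the strains being contrasted (Y minus X).
#' @return DERecord data.frame with contrast
#'   \code{"<temperature>:<strainY>-vs-<strainX>"}.
#' @export
transcriptStrainContrast <- function(tpm, design, temperature, strainX,
                                     strainY, alpha = 0.05,
                                     pseudocount = 1) {
  des <- design[design$assay == "transcript" &
                design$temperature == temperature, , drop = FALSE]
  a <- des$sample_id[des$strain == strainX]
  b <- des$sample_id[des$strain == strainY]
  if (length(a) < 2 || length(b) < 2)
    stop("need >= 2 replicates per strain at temperature ", temperature)
  m <- tpm[, c(a, b), drop = FALSE]
  m <- m[rowSums(m) > 0, , drop = FALSE]
  .welchDe(log2(m + pseudocount), a, b,
           sprintf("%s:%s-vs-%s", temperature, strainY, strainX), alpha)
}

#' Protein fold-change contrast between two strains at fixed temperature
#'
#' The 1.2-fold rule of \code{\link{proteinFcDe}} applied to mean relative
#' expressions of two strains at the same temperature (strainY minus
#' strainX).
#'
#' @inheritParams proteinFcDe
#' @param temperature \code{"control"} or \code{"stress"}.
#' @param strainX,strainY the strains being contrasted (Y minus X).
#' @return DERecord data.frame with attribute \code{"excluded"}.
#' @export
proteinFcStrainContrast <- function(relexpr, temperature, strainX, strainY,
                                    fcThreshold = 1.2) {
  r <- relexpr[relexpr$temperature == temperature, , drop = FALSE]
  a <- r[r$strain == strainX, c("gene_id", "mean_log2")]
  b <- r[r$strain == strainY, c("gene_id", "mean_log2")]
  shared <- intersect(a$gene_id, b$gene_id)
  fc <- b$mean_log2[match(shared, b$gene_id)] -
    a$mean_log2[match(shared, a$gene_id)]
  cut <- log2(fcThreshold)
  significant <- abs(fc) >= cut
  out <- data.frame(gene_id = shared,
                    contrast = sprintf("%s:%s-vs-%s", temperature, strainY,
                                       strainX),
                    log2fc = fc, stat = NA_real_, p = NA_real_, q = NA_real_,
                    significant = significant,
                    direction = ifelse(!significant | fc == 0, "none",
                                       ifelse(fc > 0, "up", "down")),
                    stringsAsFactors = FALSE)
  attr(out, "excluded") <- setdiff(union(a$gene_id, b$gene_id), shared)
  out
}

#' Welch t-test contrast of protein channels between two strains
#'
#' @inheritParams proteinTtest
#' @param temperature \code{"control"} or \code{"stress"}.
#' @param strainX,strainY the strains being contrasted (Y minus X).
#' @return DERecord data.frame with attribute \code{"skipped"}.
#' @export
proteinTtestStrainContrast <- function(channelMat, design = NULL, temperature,
                                       strainX, strainY, alpha = 0.05) {
  if (is.null(design)) design <- attr(channelMat, "design")
  des <- design[design$temperature == temperature, , drop = FALSE]
  a <- intersect(des$sample_id[des$strain == strainX], colnames(channelMat))
  b <- intersect(des$sample_id[des$strain == strainY], colnames(channelMat))
  w <- rowWelch(channelMat[, a, drop = FALSE], channelMat[, b, drop = FALSE])
  tested <- w$tested
  out <- .deRecord(rownames(channelMat)[tested],
                   sprintf("%s:%s-vs-%s", temperature, strainY, strainX),
                   (w$meanB - w$meanA)[tested], w$stat[tested], w$p[tested],
                   bhAdjust(w$p[tested]), alpha)
  attr(out, "skipped") <- rownames(channelMat)[!tested]
  out
}

#' All pairwise strain contrasts at both temperatures
#'
#' Enumerates the unordered strain pairs and runs the requested caller for
#' each pair at each temperature, concatenating the DERecord tables. With
#' three strains this yields the three comparisons per temperature
#' (e.g. H2 vs CC7, RS vs CC7, RS vs H2).
#'
#' @param x TPM matrix (transcript contrasts) or channel matrix / relexpr
#'   table (protein contrasts), matching \code{type}.
#' @param design design table.
#' @param strains strain labels (order fixes the contrast orientation).
#' @param temperatures temperatures to contrast at.
#' @param type which caller to use per pair.
#' @param ... passed to the underlying contrast function.
#' @return Concatenated DERecord data.frame across pairs and temperatures.
#' @export
pairwiseStrainContrasts <- function(x, design, strains,
                                    temperatures = c("control", "stress"),
                                    type = c("transcript", "protein-fc",
                                             "protein-ttest"), ...) {
  type <- match.arg(type)
  pairs <- utils::combn(strains, 2, simplify = FALSE)
  out <- list()
  for (tp in temperatures) {
    for (pr in pairs) {
      rec <- switch(type,
        "transcript" = transcriptStrainContrast(x, design, tp, pr[1], pr[2],
                                                ...),
        "protein-fc" = proteinFcStrainContrast(x, tp, pr[1], pr[2], ...),
        "protein-ttest" = proteinTtestStrainContrast(x, design, tp, pr[1],
                                                     pr[2], ...))
      out[[length(out) + 1L]] <- rec
    }
  }
  do.call(rbind, out)
}

#' Extract a gene panel across contrasts
#'
#' Restricts concatenated DERecord tables to a panel of genes of interest
#' (e.g. oxidative-stress-related gene models) and lays the log2 fold
#' changes out as one wide table, genes x contrasts, with missing
#' gene-contrast cells explicit (NA). Panel genes never observed in any
#' contrast are retained as all-missing rows with a warning.
#'
#' @param records DERecord data.frame (may concatenate several contrasts).
#' @param panel character vector of gene ids.
#' @return data.frame with \code{gene_id} plus one log2 fold-change column
#'   per contrast.
#' @export
extractPanel <- function(records, panel) {
  panel <- unique(as.character(panel))
  contrasts <- unique(records$contrast)
  out <- data.frame(gene_id = panel, stringsAsFactors = FALSE)
  if (length(panel) == 0) {
    for (ct in contrasts) out[[ct]] <- numeric(0)
    return(out)
  }
  for (ct in contrasts) {
    sub <- records[records$contrast == ct, , drop = FALSE]
    out[[ct]] <- sub$log2fc[match(panel, sub$gene_id)]
  }
  never <- panel[!panel %in% records$gene_id]
  if (length(never))
    warning("panel gene(s) never observed in any contrast: ",
            paste(never, collapse = ", "))
  out
}
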