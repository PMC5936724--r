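# Internal helpers shared across modules.

#' @import methods
#' @importFrom stats anova coef lm median na.omit p.adjust phyper pt rbinom
#'   rnorm rpois runif sd setNames
#' @importFrom utils read.delim write.table
#' @import data.table
NULL

.datatable.aware <- TRUE

# data.table non-standard-evaluation columns
utils::globalVariables(c(
  "intensity", "sample_id", "gene_ids", "run", "s", "off", "strain",
  "temperature", "bio_rep", "peptide_id", "nt", "ntech", "nbio",
  "maxWithin", "keep", "gene_id", "value", "total"))

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

# Row-wise Welch two-sample t-test on two matrices (rows = genes).
# Returns mean/variance/counts per group plus statistic, df and two-sided p.
# Group B minus group A is the reported direction of effect.
# Degenerate rows: both variances zero -> p = 1 if means equal, p = 0 otherwise;
# fewer than 2 observations in either group -> NA.
rowWelch <- function(a, b) {
  a <- as.matrix(a)
  b <- as.matrix(b)
  na <- rowSums(!is.na(a))
  nb <- rowSums(!is.na(b))
  ma <- rowMeans(a, na.rm = TRUE)
  mb <- rowMeans(b, na.rm = TRUE)
  va <- rowSums((a - ma)^2, na.rm = TRUE) / pmax(na - 1, 1)
  vb <- rowSums((b - mb)^2, na.rm = TRUE) / pmax(nb - 1, 1)
  ok <- na >= 2 & nb >= 2
  sa2 <- va / na
  sb2 <- vb / nb
  s2 <- sa2 + sb2
  diffm <- mb - ma
  stat <- diffm / sqrt(s2)
  df <- s2^2 / (sa2^2 / (na - 1) + sb2^2 / (nb - 1))
  p <- 2 * pt(abs(stat), df, lower.tail = FALSE)
  zero <- ok & s2 == 0
  stat[zero & diffm == 0] <- 0
  p[zero & diffm == 0] <- 1
  stat[zero & diffm != 0] <- sign(diffm[zero & diffm != 0]) * Inf
  p[zero & diffm != 0] <- 0
  df[zero] <- NA_real_
  stat[!ok] <- NA_real_
  p[!ok] <- NA_real_
  df[!ok] <- NA_real_
  list(meanA = ma, meanB = mb, nA = na, nB = nb,
       stat = stat, df = df, p = p, tested = ok)
}

# DERecord assembly shared by the transcript and protein callers.
.deRecord <- function(gene_id, contrast, log2fc, stat, p, q, alpha) {
  significant <- !is.na(q) & q < alpha
  direction <- ifelse(!significant | log2fc == 0, "none",
                      ifelse(log2fc > 0, "up", "down"))
  data.frame(gene_id = gene_id, contrast = contrast, log2fc = log2fc,
             stat = stat, p = p, q = q, significant = significant,
             direction = direction, row.names = NULL,
             stringsAsFactors = FALSE)
}

.checkCols <- function(df, cols, what) {
  miss <- setdiff(cols, colnames(df))
  if (length(miss))
    stop(what, " is missing required column(s): ", paste(miss, collapse = ", "))
  invisible(df)
}
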