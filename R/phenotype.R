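# Reactive oxygen species (ROS) assays: dye fluorescence normalized per
# symbiont cell, compared between temperatures within strain and context
# (in-host versus isolated symbionts).

#' Normalize ROS fluorescence by cell counts
#'
#' Adds a \code{normalized} column (fluorescence per symbiont cell) to a
#' ROS measurement table. Rows with nonpositive cell counts cannot be
#' normalized; they are removed with a warning and returned in the
#' \code{"rejected"} attribute.
#'
#' @param ros data.frame with columns \code{strain}, \code{temperature},
#'   \code{context}, \code{replicate}, \code{fluorescence},
#'   \code{cell_count}.
#' @return The table with a \code{normalized} column; attribute
#'   \code{"rejected"} holds the dropped rows.
#' @export
normalizeRos <- function(ros) {
  .checkCols(ros, c("strain", "temperature", "context", "replicate",
                    "fluorescence", "cell_count"), "ROS table")
  if (any(ros$fluorescence < 0, na.rm = TRUE))
    stop("fluorescence must be nonnegative")
  bad <- !is.finite(ros$cell_count) | ros$cell_count <= 0
  rejected <- ros[bad, , drop = FALSE]
  if (nrow(rejected))
    warning(nrow(rejected), " row(s) rejected: nonpositive cell count")
  out <- ros[!bad, , drop = FALSE]
  out$normalized <- out$fluorescence / out$cell_count
  rownames(out) <- NULL
  attr(out, "rejected") <- rejected
  out
}

#' Compare per-cell ROS between temperatures
#'
#' Welch t-test of stress versus control normalized (per-cell) fluorescence
#' for one strain and measurement context, with group means and standard
#' errors for error-bar style reporting.
#'
#' @param ros normalized ROS table from \code{\link{normalizeRos}}.
#' @param strain strain label.
#' @param context \code{"in_hospite"} or \code{"isolate"}.
#' @param alpha significance level.
#' @return One-row data.frame: \code{strain}, \code{context},
#'   \code{mean_control}, \code{mean_stress}, \code{se_control},
#'   \code{se_stress}, \code{difference} (stress minus control),
#'   \code{stat}, \code{p}, \code{significant}.
#' @export
compareRos <- function(ros, strain, context = "in_hospite", alpha = 0.05) {
  .checkCols(ros, c("strain", "temperature", "context", "normalized"),
             "normalized ROS table")
  sub <- ros[ros$strain == strain & ros$context == context, , drop = FALSE]
  ctl <- sub$normalized[sub$temperature == "control"]
  str <- sub$normalized[sub$temperature == "stress"]
  if (length(ctl) < 2 || length(str) < 2)
    stop("need >= 2 normalized replicates per temperature for ", strain,
         " (", context, ")")
  w <- rowWelch(matrix(ctl, 1), matrix(str, 1))
  data.frame(strain = strain, context = context,
             mean_control = mean(ctl), mean_stress = mean(str),
             se_control = sd(ctl) / sqrt(length(ctl)),
             se_stress = sd(str) / sqrt(length(str)),
             difference = mean(str) - mean(ctl),
             stat = w$stat, p = w$p, significant = !is.na(w$p) & w$p < alpha,
             stringsAsFactors = FALSE, row.names = NULL)
}
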