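# GO term over-representation against a custom background of expressed gene
# models. Classic one-sided Fisher / hypergeometric testing; the background
# is restricted to genes with detectable expression so that enrichment is
# not biased towards terms attached to expressed genes. Following the
# original analysis choice, no multiple-testing adjustment is applied and a
# term is only reported when p < 0.05 and it occurs at least 5 times in the
# background.

#' Propagate annotations up the ontology
#'
#' Extends each gene's term set with all ancestors of its terms under the
#' \code{is_a} relation (the GO true-path rule), so that annotation counts
#' at general terms include genes annotated at more specific descendants.
#'
#' @param annotations named list: gene id -> character vector of term ids.
#' @param edges data.frame with columns \code{child}, \code{parent}
#'   (\code{is_a} edges); must be acyclic.
#' @return Named list of propagated term sets.
#' @export
propagateAnnotations <- function(annotations, edges) {
  .checkCols(edges, c("child", "parent"), "edge table")
  parents <- split(as.character(edges$parent), as.character(edges$child))
  anc <- new.env(parent = emptyenv())
  state <- new.env(parent = emptyenv())  # 1 = visiting, 2 = done
  ancestors <- function(term) {
    st <- state[[term]]
    if (identical(st, 1L)) stop("cycle detected in ontology at term ", term)
    if (identical(st, 2L)) return(anc[[term]])
    state[[term]] <- 1L
    ps <- parents[[term]]
    res <- character(0)
    for (p in ps) res <- union(res, c(p, ancestors(p)))
    anc[[term]] <- res
    state[[term]] <- 2L
    res
  }
  for (term in union(names(parents), unique(as.character(edges$parent))))
    ancestors(term)
  lapply(annotations, function(terms) {
    terms <- unique(as.character(terms))
    out <- terms
    for (t in terms) out <- union(out, ancestors(t))
    sort(out)
  })
}

#' GO term over-representation against an expressed background
#'
#' One-sided hypergeometric test per term occurring in the background: with
#' \code{N} background genes, \code{K} of them annotated with the term,
#' \code{n} genes in the differential set and \code{k} of those annotated,
#' the p-value is the upper tail \eqn{P(X \ge k)} for
#' \eqn{X \sim Hypergeom(N, K, n)}. No multiple-testing adjustment is
#' applied (the tests on a term DAG are not independent); instead a term is
#' flagged \code{reported} only when \code{p < alpha} and its background
#' count is at least \code{minBackground}.
#'
#' @param deSet character vector of differentially expressed gene ids; must
#'   be a subset of \code{background}.
#' @param background character vector of expressed gene ids (the universe).
#' @param annotations named list gene id -> term ids (pre-propagated, or
#'   see \code{\link{propagateAnnotations}}).
#' @param alpha reporting threshold on the raw p-value.
#' @param minBackground minimum background occurrences for reporting.
#' @return EnrichmentRecord data.frame: \code{term}, \code{k}, \code{K},
#'   \code{n}, \code{N}, \code{p}, \code{reported}, ordered by p.
#' @export
fisherEnrichment <- function(deSet, background, annotations, alpha = 0.05,
                             minBackground = 5) {
  deSet <- unique(as.character(deSet))
  background <- unique(as.character(background))
  if (!all(deSet %in% background))
    stop("differential set is not a subset of the background: ",
         paste(utils::head(setdiff(deSet, background), 5), collapse = ", "))
  ann <- annotations[intersect(names(annotations), background)]
  if (!length(ann))
    return(data.frame(term = character(0), k = integer(0), K = integer(0),
                      n = integer(0), N = integer(0), p = numeric(0),
                      reported = logical(0)))
  long <- data.frame(
    gene = rep(names(ann), lengths(ann)),
    term = unlist(ann, use.names = FALSE), stringsAsFactors = FALSE)
  long <- unique(long)
  Ktab <- table(long$term)
  ktab <- table(long$term[long$gene %in% deSet])
  terms <- names(Ktab)
  K <- as.integer(Ktab)
  k <- as.integer(ktab[terms])
  k[is.na(k)] <- 0L
  N <- length(background)
  n <- length(deSet)
  p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  out <- data.frame(term = terms, k = k, K = K, n = n, N = N, p = p,
                    reported = p < alpha & K >= minBackground,
                    stringsAsFactors = FALSE)
  out <- out[order(out$p, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a minimal OBO ontology
#'
#' Parses only the \code{id:} and \code{is_a:} lines of \code{[Term]}
#' stanzas, returning the edge table used by
#' \code{\link{propagateAnnotations}}. Everything else in the file is
#' ignored.
#'
#' @param path path to an OBO file.
#' @return data.frame with columns \code{child}, \code{parent}.
#' @export
readObo <- function(path) {
  lines <- readLines(path, warn = FALSE)
  child <- NA_character_
  from <- character(0)
  to <- character(0)
  inTerm <- FALSE
  for (ln in lines) {
    ln <- trimws(ln)
    if (startsWith(ln, "[")) {
      inTerm <- identical(ln, "[Term]")
      child <- NA_character_
    } else if (inTerm && startsWith(ln, "id:")) {
      child <- trimws(sub("^id:", "", ln))
    } else if (inTerm && startsWith(ln, "is_a:") && !is.na(child)) {
      parent <- trimws(sub("!.*$", "", sub("^is_a:", "", ln)))
      from <- c(from, child)
      to <- c(to, parent)
    }
  }
  data.frame(child = from, parent = to, stringsAsFactors = FALSE)
}
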