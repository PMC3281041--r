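# Hypergeometric term enrichment of DE gene sets.

#' Construct an annotation set
#'
#' @param terms named list, term id -> character vector of annotated gene
#'   ids.
#' @return an [AnnotationSet-class]; the background universe is the union of
#'   all annotated genes.
#' @export
annotationSet <- function(terms) {
  if (!length(terms)) stop("annotation must contain at least one term")
  terms <- lapply(terms, function(g) unique(as.character(g)))
  new("AnnotationSet", terms = terms,
      universe = unique(unlist(terms, use.names = FALSE)))
}

#' Upper-tail hypergeometric enrichment probability
#'
#' Probability of observing at least \code{m} annotated genes in the DE set
#' when \code{n} genes are drawn from a universe of \code{N} annotated
#' genes, \code{M} of which carry the term:
#' \deqn{p = \sum_{i=m}^{\min(n,M)} \frac{\binom{M}{i}\binom{N-M}{n-i}}
#' {\binom{N}{n}}}{p = sum_{i=m..min(n,M)} C(M,i) C(N-M,n-i) / C(N,n)}
#' evaluated in log space. \code{m = 0} returns exactly 1 (the upper tail
#' covers the full support).
#'
#' @param N number of genes in the annotated background universe.
#' @param n number of DE genes within the universe.
#' @param M number of universe genes carrying the term.
#' @param m number of DE genes carrying the term.
#' @return upper-tail probability in (0, 1].
#' @export
#' @examples
#' hypergeomEnrichTerm(N = 10, n = 4, M = 5, m = 4)  # 5/210
hypergeomEnrichTerm <- function(N, n, M, m) {
  .assertCount(c(N, n, M, m), "N,n,M,m")
  if (M > N || n > N) stop("require M <= N and n <= N")
  if (m > min(n, M)) stop("require m <= min(n, M)")
  if (m == 0) return(1)
  is <- m:min(n, M)
  lt <- lchoose(M, is) + lchoose(N - M, n - is) - lchoose(N, n)
  min(1, max(exp(logSumExp(lt)), 1e-300))
}

#' Hypergeometric enrichment of every annotated term
#'
#' For each term, tests over-representation of the DE gene set within the
#' annotated background universe (genes carrying any annotation), corrects
#' the p-values for multiplicity and flags significant terms at
#' \code{corrected p < alpha}. DE genes outside the universe are dropped
#' with a warning.
#'
#' @param annotation an [AnnotationSet-class].
#' @param deGenes character vector of DE gene ids.
#' @param correction \code{"BH"} (default; matches FDR-style thresholds) or
#'   \code{"bonferroni"}.
#' @param alpha significance threshold on the corrected p-value
#'   (default 0.05).
#' @return data.frame with columns \code{term}, \code{N}, \code{n},
#'   \code{M}, \code{m}, \code{pValue}, \code{correctedP},
#'   \code{significant}, ordered by increasing p.
#' @export
enrichAllTerms <- function(annotation, deGenes,
                           correction = c("BH", "bonferroni"), alpha = 0.05) {
  stopifnot(is(annotation, "AnnotationSet"))
  correction <- match.arg(correction)
  deGenes <- unique(as.character(deGenes))
  outside <- setdiff(deGenes, annotation@universe)
  if (length(outside)) {
    warning(length(outside), " DE gene(s) without annotation dropped from ",
            "the enrichment universe")
    deGenes <- setdiff(deGenes, outside)
  }
  N <- length(annotation@universe)
  n <- length(deGenes)
  terms <- annotation@terms
  M <- lengths(terms)
  m <- vapply(terms, function(g) sum(g %in% deGenes), 0L)
  p <- vapply(seq_along(terms), function(i)
    hypergeomEnrichTerm(N, n, M[i], m[i]), 0)
  cp <- stats::p.adjust(p, method = if (correction == "BH") "BH" else "bonferroni")
  out <- data.frame(term = names(terms), N = N, n = n,
                    M = as.integer(M), m = m, pValue = p, correctedP = cp,
                    significant = cp < alpha,
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(out$pValue, out$term), , drop = FALSE]
}
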