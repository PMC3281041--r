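# Differential expression between two tag libraries: Audic-Claverie exact
# conditional test, log2 expression ratios, BH FDR and threshold calls.

# log per-point mass of the conditional distribution of y given x when the
# two libraries have sizes n1 and n2 (r = n2/n1):
#   p(y | x) = r^y * (x+y)! / (x! y! (1+r)^(x+y+1))
# which is the NegBinomial(size = x+1, prob = 1/(1+r)) mass in y.
.acLogMass <- function(ks, x, logr, log1pr) {
  ks * logr + lchoose(x + ks, ks) - (x + ks + 1) * log1pr
}

# log P(Y >= y | x): summed upward in log space in chunks until the terms
# are decaying and the remaining contribution is below relative 1e-17
.acLogUpper <- function(x, y, logr, log1pr) {
  chunk <- 2048L
  k0 <- y
  logS <- -Inf
  repeat {
    ks <- k0:(k0 + chunk - 1L)
    lt <- .acLogMass(ks, x, logr, log1pr)
    logS <- logSumExp(c(logS, logSumExp(lt)))
    decaying <- lt[chunk] < lt[1L]
    if (decaying && (lt[chunk] - logS) < log(1e-17)) break
    k0 <- k0 + chunk
    if (k0 > y + 5e7) stop("Audic-Claverie upper tail failed to converge")
  }
  logS
}

#' Audic-Claverie two-sided p-value for two tag counts
#'
#' Exact conditional test for a difference between counts \code{x} and
#' \code{y} of one tag (or gene) observed in two libraries of total sizes
#' \code{n1} and \code{n2}. Conditional on \code{x}, the distribution of
#' \code{y} has mass \deqn{p(y|x) = (N_2/N_1)^y \frac{(x+y)!}{x!\,y!\,
#' (1+N_2/N_1)^{x+y+1}}}{p(y|x) = r^y (x+y)!/(x! y! (1+r)^(x+y+1))} and the
#' two-sided p-value is the doubled smaller tail, capped at 1:
#' \code{min(1, 2 min(P(Y <= y | x), P(Y >= y | x)))}. Tail sums are
#' accumulated in log space and are stable for counts up to 10^6; p-values
#' below 1e-300 are truncated to 1e-300 to stay in (0, 1].
#'
#' @param x,y non-negative integer counts in libraries A and B (vectorized).
#' @param n1,n2 total tag counts (library sizes) of A and B.
#' @return numeric vector of two-sided p-values in (0, 1].
#' @export
#' @examples
#' acPValue(0, 0, 1e6, 1e6)     # 1: the two libraries agree trivially
#' acPValue(10, 100, 5e5, 5e5)  # strong evidence for a difference
acPValue <- function(x, y, n1, n2) {
  .assertCount(x, "x"); .assertCount(y, "y")
  if (any(c(n1, n2) < 1)) stop("library sizes must be >= 1")
  m <- max(length(x), length(y))
  x <- rep_len(as.numeric(x), m); y <- rep_len(as.numeric(y), m)
  n1 <- rep_len(as.numeric(n1), m); n2 <- rep_len(as.numeric(n2), m)
  logr <- log(n2) - log(n1)
  log1pr <- log1p(n2 / n1)
  vapply(seq_len(m), function(i) {
    logLower <- logSumExp(.acLogMass(0:y[i], x[i], logr[i], log1pr[i]))
    logUpper <- .acLogUpper(x[i], y[i], logr[i], log1pr[i])
    p <- 2 * exp(min(logLower, logUpper))
    min(1, max(p, 1e-300))
  }, 0)
}

#' Conditional tail probabilities of the Audic-Claverie test
#'
#' \code{lower = P(Y <= y | x)} and \code{upper = P(Y >= y | x)} under the
#' conditional distribution used by [acPValue()]. Useful for diagnostics and
#' for validating the per-point mass (\code{lower + upper - 1} is the mass
#' at \code{y}, and \code{lower} tends to 1 as \code{y} grows).
#'
#' @param x,y non-negative integer counts (scalars).
#' @param n1,n2 library sizes.
#' @return named numeric vector with \code{lower} and \code{upper}.
#' @export
acTailProbs <- function(x, y, n1, n2) {
  .assertCount(x, "x"); .assertCount(y, "y")
  stopifnot(length(x) == 1L, length(y) == 1L, n1 >= 1, n2 >= 1)
  logr <- log(n2) - log(n1)
  log1pr <- log1p(n2 / n1)
  c(lower = exp(logSumExp(.acLogMass(0:y, x, logr, log1pr))),
    upper = exp(.acLogUpper(x, y, logr, log1pr)))
}

#' Log2 expression ratio between two libraries
#'
#' \code{log2(((y + pc)/n2) / ((x + pc)/n1))} — the library-size-normalized
#' proportion ratio (equivalent to the TPM ratio), oriented as library B
#' over library A. A pseudocount regularizes zero counts; with
#' \code{pseudocount = 0} both counts must be positive.
#'
#' @param x,y counts in libraries A and B (vectorized).
#' @param n1,n2 library sizes.
#' @param pseudocount non-negative regularizer added to both counts
#'   (default 0.5).
#' @return numeric vector of log2 ratios.
#' @export
#' @examples
#' log2Ratio(10, 20, 1e6, 1e6, pseudocount = 0)  # 1
log2Ratio <- function(x, y, n1, n2, pseudocount = 0.5) {
  if (pseudocount < 0) stop("'pseudocount' must be >= 0")
  if (pseudocount == 0 && any(x == 0 | y == 0))
    stop("zero counts require a positive pseudocount")
  log2(((y + pseudocount) / n2) / ((x + pseudocount) / n1))
}

#' Benjamini-Hochberg q-values
#'
#' Step-up FDR adjustment \code{q_(i) = min_(j >= i) p_(j) * m / j}, capped
#' at 1 and returned in input order (delegates to
#' \code{stats::p.adjust(method = "BH")} after validating the input domain).
#'
#' @param p numeric vector of p-values in (0, 1].
#' @return numeric vector of q-values, same order as \code{p}.
#' @export
#' @examples
#' bhFDR(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
bhFDR <- function(p) {
  if (any(is.na(p)) || any(p <= 0) || any(p > 1))
    stop("p-values must lie in (0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Call differentially expressed genes between two libraries
#'
#' Computes, per gene, the Audic-Claverie p-value on the unambiguous tag
#' counts, the BH q-value within the comparison, and the log2 ratio of
#' normalized proportions (B over A; p-values use the raw counts, only the
#' ratio is regularized by the pseudocount). A gene is called \code{up} when
#' \code{log2Ratio >= lfcThreshold} and the significance criterion holds
#' (\code{sigMode = "fdr"}: q < alpha; \code{sigMode = "p"}: p <= alpha),
#' \code{down} symmetrically, otherwise \code{ns}.
#'
#' @param exprA,exprB [ExpressionTable-class] objects over the same gene
#'   universe (A = earlier stage, B = later stage).
#' @param alpha significance threshold (default 0.001).
#' @param lfcThreshold minimum absolute log2 ratio (default 1).
#' @param sigMode \code{"fdr"} (default) thresholds the BH q-value,
#'   \code{"p"} the raw p-value.
#' @param pseudocount pseudocount for the log2 ratio (default 0.5).
#' @return data.frame with columns \code{gene}, \code{x}, \code{y},
#'   \code{tpmA}, \code{tpmB}, \code{log2Ratio}, \code{pValue},
#'   \code{qValue}, \code{call}; comparison metadata in
#'   \code{attr(, "comparison")}.
#' @seealso [summarizeDECalls()]
#' @export
callDEGenes <- function(exprA, exprB, alpha = 0.001, lfcThreshold = 1,
                        sigMode = c("fdr", "p"), pseudocount = 0.5) {
  stopifnot(is(exprA, "ExpressionTable"), is(exprB, "ExpressionTable"))
  sigMode <- match.arg(sigMode)
  if (!identical(exprA@gene, exprB@gene)) {
    onlyA <- setdiff(exprA@gene, exprB@gene)
    onlyB <- setdiff(exprB@gene, exprA@gene)
    if (length(onlyA) || length(onlyB))
      stop("gene universes differ; only in A: ",
           paste(utils::head(onlyA, 5L), collapse = ","),
           "; only in B: ", paste(utils::head(onlyB, 5L), collapse = ","))
    exprB <- computeTPM(tagCopies(exprB)[exprA@gene], exprB@cleanTotal,
                        libraryId(exprB))
  }
  x <- exprA@copies; y <- exprB@copies
  n1 <- exprA@cleanTotal; n2 <- exprB@cleanTotal
  p <- acPValue(x, y, n1, n2)
  q <- bhFDR(p)
  lr <- log2Ratio(x, y, n1, n2, pseudocount)
  sig <- if (sigMode == "fdr") q < alpha else p <= alpha
  call <- ifelse(sig & lr >= lfcThreshold, "up",
          ifelse(sig & lr <= -lfcThreshold, "down", "ns"))
  out <- data.frame(gene = exprA@gene, x = x, y = y,
                    tpmA = exprA@tpm, tpmB = exprB@tpm,
                    log2Ratio = lr, pValue = p, qValue = q, call = call,
                    stringsAsFactors = FALSE)
  attr(out, "comparison") <- list(
    a = libraryId(exprA), b = libraryId(exprB), alpha = alpha,
    lfcThreshold = lfcThreshold, sigMode = sigMode, pseudocount = pseudocount)
  out
}

#' Summarize up/down calls of a DE comparison
#'
#' @param de the data.frame returned by [callDEGenes()], or a character
#'   vector of calls (\code{up}/\code{down}/\code{ns}).
#' @return named list with \code{up}, \code{down} and \code{total}
#'   (\code{total = up + down}, the number of DE genes).
#' @export
#' @examples
#' summarizeDECalls(c("up", "down", "ns", "up"))
summarizeDECalls <- function(de) {
  calls <- if (is.data.frame(de)) de$call else de
  if (!all(calls %in% c("up", "down", "ns")))
    stop("calls must be 'up', 'down' or 'ns'")
  up <- sum(calls == "up")
  down <- sum(calls == "down")
  list(up = up, down = down, total = up + down)
}
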