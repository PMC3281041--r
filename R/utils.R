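#' Log-sum-exp of a vector of log values
#'
#' Numerically stable evaluation of \code{log(sum(exp(lx)))}, used by the
#' exact-test tail sums so that probabilities far below double underflow in
#' linear space remain representable in log space.
#'
#' @param lx numeric vector of log-scale values (may contain \code{-Inf}).
#' @return a single numeric, \code{-Inf} for an empty vector.
#' @keywords internal
logSumExp <- function(lx) {
  if (length(lx) == 0L) return(-Inf)
  m <- max(lx)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(lx - m)))
}

#' Round half away from zero
#'
#' Commercial ("half-up") rounding at a fixed number of decimals. Library
#' statistics tables in tag-sequencing reports are conventionally printed with
#' two decimals rounded half-up, which differs from R's banker's rounding in
#' \code{round()}.
#'
#' @param x numeric vector (non-negative in all package uses).
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
#' @examples
#' roundHalfUp(22.875, 2)  # 22.88, where round() would give 22.87 or 22.88
roundHalfUp <- function(x, digits = 2L) {
  s <- sign(x)
  p <- 10^digits
  s * floor(abs(x) * p + 0.5) / p
}

#' Percentage of a denominator, rounded half-up to two decimals
#'
#' @param num numerator count(s).
#' @param den denominator count(s).
#' @param digits decimals to keep (default 2).
#' @return percentage value(s); \code{NA} where the denominator is zero (an
#'   undefined ratio is reported as missing, never as 0).
#' @export
#' @examples
#' percentOf(1381410, 6037779)  # 22.88
percentOf <- function(num, den, digits = 2L) {
  out <- rep(NA_real_, length(num))
  ok <- !is.na(den) & den > 0
  out[ok] <- roundHalfUp(100 * num[ok] / den[ok], digits)
  out
}

# shared alphabet for tag sequences
.DNA_BASES <- c("A", "C", "G", "T")

# named character sequences from a DNAStringSet or named character vector
# (base as.character() silently drops names from character vectors)
.asNamedSeqs <- function(genes) {
  nm <- names(genes)
  seqs <- as.character(genes)
  names(seqs) <- nm
  seqs
}

.assertCount <- function(x, name) {
  if (any(is.na(x)) || any(x < 0) || any(x != floor(x)))
    stop(sprintf("'%s' must contain non-negative integers", name), call. = FALSE)
  invisible(x)
}
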