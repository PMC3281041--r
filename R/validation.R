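# Validation-side statistics: comparative-CT qPCR quantification and
# knockdown effect sizes.

#' Relative expression by the comparative CT (2^-ddCt) method
#'
#' Per sample, \code{dCt = Ct_target - Ct_reference} (reference = the
#' housekeeping gene, e.g. rp49); \code{ddCt} is the sample's dCt minus the
#' mean dCt of the control group, and the fold change is \code{2^-ddCt}.
#' Adding a constant to every CT (target and reference alike) leaves the
#' fold changes unchanged.
#'
#' @param treated data.frame of treated samples with numeric columns
#'   \code{ctTarget} and \code{ctReference} (optional \code{sample} labels).
#' @param control data.frame of control samples, same columns; at least one
#'   row (defines the dCt baseline as the group mean).
#' @return list with \code{perSample} (data.frame: sample, dCt, ddCt, fold),
#'   \code{meanFold} and \code{seFold} (standard error of the mean fold,
#'   \code{NA} for a single treated sample).
#' @export
#' @examples
#' treated <- data.frame(ctTarget = 24, ctReference = 18)
#' control <- data.frame(ctTarget = 26, ctReference = 18)
#' ddctFoldChange(treated, control)$perSample$fold  # 2^-(6-8) = 4
ddctFoldChange <- function(treated, control) {
  for (d in list(treated, control)) {
    if (!all(c("ctTarget", "ctReference") %in% names(d)))
      stop("CT tables need columns 'ctTarget' and 'ctReference'")
    ct <- c(d$ctTarget, d$ctReference)
    if (any(!is.finite(ct)) || any(ct <= 0))
      stop("CT values must be finite and positive")
  }
  if (nrow(control) < 1L) stop("at least one control sample is required")
  dctControl <- mean(control$ctTarget - control$ctReference)
  dct <- treated$ctTarget - treated$ctReference
  ddct <- dct - dctControl
  fold <- 2^(-ddct)
  labs <- if (!is.null(treated$sample)) as.character(treated$sample)
          else paste0("sample", seq_along(dct))
  list(
    perSample = data.frame(sample = labs, dCt = dct, ddCt = ddct, fold = fold,
                           stringsAsFactors = FALSE),
    meanFold = mean(fold),
    seFold = if (length(fold) > 1L) stats::sd(fold) / sqrt(length(fold))
             else NA_real_
  )
}

#' Knockdown effect size as percent of control, with a t-test
#'
#' \code{100 * mean(treatment) / mean(control)} together with a two-sided
#' two-sample Student's t-test (pooled variance by default; Welch
#' selectable). Scaling both groups by a common positive factor leaves the
#' percentage and the t statistic unchanged.
#'
#' @param treatment numeric measurements of the treated group.
#' @param control numeric measurements of the control group.
#' @param varEqual pooled-variance Student's t (default TRUE); FALSE gives
#'   the Welch test.
#' @return list with \code{percent} (\code{NA} when the control mean is 0),
#'   \code{t}, \code{df} and \code{pValue} (all \code{NA} with a warning
#'   when either group has fewer than 2 values).
#' @export
#' @examples
#' percentOfControl(c(2.0, 2.2, 2.4), c(3.8, 4.0, 4.2))$percent  # 55
percentOfControl <- function(treatment, control, varEqual = TRUE) {
  treatment <- as.numeric(treatment); control <- as.numeric(control)
  if (any(!is.finite(c(treatment, control))))
    stop("measurements must be finite")
  mc <- mean(control)
  percent <- if (mc == 0) {
    warning("control mean is 0; percent of control is undefined")
    NA_real_
  } else 100 * mean(treatment) / mc
  if (length(treatment) < 2L || length(control) < 2L) {
    warning("need >= 2 values per group for the t-test")
    return(list(percent = percent, t = NA_real_, df = NA_real_,
                pValue = NA_real_))
  }
  tt <- stats::t.test(treatment, control, var.equal = varEqual,
                      alternative = "two.sided")
  list(percent = percent, t = unname(tt$statistic),
       df = unname(tt$parameter), pValue = tt$p.value)
}
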