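# TPM quantification, expression distributions and saturation analysis.

#' Normalize per-gene tag counts to TPM
#'
#' \code{tpm = copies * 1e6 / cleanTotal} — transcripts per million clean
#' tags. The denominator is the clean-tag total of the library (all clean
#' tags, not only the mapped ones); genes with zero copies are retained with
#' TPM 0.
#'
#' @param counts named numeric vector, gene -> unambiguous tag copies
#'   (>= 0; zero-copy genes allowed).
#' @param cleanTotal total clean tags of the library (> 0).
#' @param libraryId library label.
#' @return an [ExpressionTable-class].
#' @export
#' @examples
#' computeTPM(c(geneA = 5), cleanTotal = 1e6)  # TPM 5
computeTPM <- function(counts, cleanTotal, libraryId = "library") {
  if (length(cleanTotal) != 1L || is.na(cleanTotal) || cleanTotal <= 0)
    stop("'cleanTotal' must be a single positive number")
  if (is.null(names(counts))) stop("'counts' must be named by gene id")
  .assertCount(counts, "counts")
  new("ExpressionTable",
      libraryId = libraryId,
      gene = names(counts),
      copies = as.numeric(counts),
      tpm = as.numeric(counts) * 1e6 / cleanTotal,
      cleanTotal = as.numeric(cleanTotal))
}

#' Expression table from a mapping result
#'
#' Convenience wrapper: takes the per-gene unambiguous copies of a
#' [MappingResult-class], fills zeros for the remaining genes of the
#' reference universe, and normalizes by the clean total of the library.
#'
#' @param mapping a [MappingResult-class].
#' @param clean the [CleanTagTable-class] the mapping was computed from
#'   (provides the TPM denominator).
#' @param genes character vector of all reference gene ids.
#' @return an [ExpressionTable-class] over all \code{genes}.
#' @export
expressionFromMapping <- function(mapping, clean, genes) {
  stopifnot(is(mapping, "MappingResult"), is(clean, "CleanTagTable"))
  gc <- geneCounts(mapping)
  counts <- stats::setNames(numeric(length(genes)), genes)
  known <- gc$gene %in% genes
  if (!all(known))
    stop("mapping contains genes absent from the reference universe: ",
         paste(utils::head(gc$gene[!known], 5L), collapse = ", "))
  counts[gc$gene] <- gc$copies
  computeTPM(counts, cleanTotal(clean), libraryId = libraryId(clean))
}

#' Copy-number distribution on total and distinct bases
#'
#' Bins tag copy numbers (for a [CleanTagTable-class]) or per-gene copies
#' (for an [ExpressionTable-class]; zero-copy genes are excluded as
#' undetected) into half-open intervals \code{[e1,e2), ..., [ek,Inf)} and
#' reports, per bin, the fraction of total copies and the fraction of
#' distinct tags/genes. An underflow bin is prepended automatically when
#' values below the first edge exist. Fractions sum to 1 on each basis.
#'
#' @param x a CleanTagTable or ExpressionTable.
#' @param binEdges strictly increasing numeric edges; the default
#'   \code{c(2, 5, 10, 20, 50, 100, Inf)} reproduces the conventional
#'   copy-number categories of tag-library reports.
#' @return data.frame with columns \code{bin}, \code{totalFraction},
#'   \code{distinctFraction}; zero-filled for empty input.
#' @export
expressionDistribution <- function(x, binEdges = c(2, 5, 10, 20, 50, 100, Inf)) {
  if (is.unsorted(binEdges, strictly = TRUE))
    stop("'binEdges' must be strictly increasing")
  values <- if (is(x, "CleanTagTable")) as.numeric(x@counts)
            else if (is(x, "ExpressionTable")) x@copies[x@copies > 0]
            else stop("'x' must be a CleanTagTable or ExpressionTable")
  edges <- binEdges
  if (length(values) && min(values) < edges[1L]) edges <- c(-Inf, edges)
  last <- length(edges)
  labs <- character(last - 1L + 1L)
  labs <- c(sprintf("[%s,%s)", edges[-last], edges[-1L]),
            sprintf(">=%s", edges[last]))
  if (is.infinite(edges[last])) {
    labs <- sprintf("[%s,%s)", edges[-last], edges[-1L])
  }
  nb <- length(labs)
  if (!length(values)) {
    return(data.frame(bin = labs, totalFraction = numeric(nb),
                      distinctFraction = numeric(nb), stringsAsFactors = FALSE))
  }
  idx <- findInterval(values, edges)
  idx[idx > nb] <- nb  # values at/above the last finite edge
  tot <- vapply(seq_len(nb), function(b) sum(values[idx == b]), 0)
  dis <- vapply(seq_len(nb), function(b) sum(idx == b), 0)
  data.frame(bin = labs,
             totalFraction = tot / sum(values),
             distinctFraction = dis / length(values),
             stringsAsFactors = FALSE)
}

#' Gene-detection saturation curve
#'
#' For each subsample size, draws tag copies without replacement from the
#' clean library (seeded), and counts the genes detected with at least one
#' unambiguously mapping tag. Because the mapping of a distinct tag does not
#' depend on its copy number, the classification of each distinct tag is
#' computed once up front and reused across subsamples; the result is
#' identical to re-mapping every subsample. Subsamples are replicated and
#' averaged.
#'
#' @param clean a [CleanTagTable-class].
#' @param index a [VirtualTagIndex-class].
#' @param sizes numeric vector of subsample sizes (each <= clean total;
#'   size 0 detects 0 genes).
#' @param seed integer seed for the subsampling.
#' @param reps seeded replicates per size (default 3), reporting the mean.
#' @return data.frame with columns \code{size} and \code{detectedGenes}
#'   (mean over replicates).
#' @export
saturationCurve <- function(clean, index, sizes, seed = 1L, reps = 3L) {
  stopifnot(is(clean, "CleanTagTable"))
  total <- cleanTotal(clean)
  if (any(sizes > total))
    stop("subsample size exceeds the clean total (", total, ")")
  .assertCount(sizes, "sizes")
  counts <- as.numeric(clean@counts)
  perTag <- .classifyTags(names(clean@counts), index)
  unGene <- ifelse(perTag$category == "gene_unambiguous", perTag$genes,
                   NA_character_)
  cum <- c(0, cumsum(counts))
  set.seed(seed)
  detected <- vapply(sizes, function(s) {
    mean(vapply(seq_len(reps), function(r) {
      if (s == 0) return(0L)
      ids <- sample.int(total, s)
      tagIdx <- findInterval(ids - 0.5, cum)
      length(unique(stats::na.omit(unGene[unique(tagIdx)])))
    }, 0L))
  }, 0)
  data.frame(size = sizes, detectedGenes = detected)
}

#' Combine per-library expression tables into a SummarizedExperiment
#'
#' Assembles the per-gene copy and TPM vectors of several libraries into a
#' [SummarizedExperiment::SummarizedExperiment] with assays \code{counts}
#' and \code{tpm} and per-library \code{cleanTotal} in the column data.
#'
#' @param tables list of [ExpressionTable-class] objects over the same gene
#'   universe.
#' @return a SummarizedExperiment (genes x libraries).
#' @export
expressionSummarizedExperiment <- function(tables) {
  stopifnot(length(tables) >= 1L)
  genes <- tables[[1L]]@gene
  for (t in tables) {
    if (!identical(t@gene, genes))
      stop("all expression tables must share one gene universe")
  }
  ids <- vapply(tables, libraryId, "")
  counts <- vapply(tables, function(t) t@copies, numeric(length(genes)))
  tpm <- vapply(tables, function(t) t@tpm, numeric(length(genes)))
  dimnames(counts) <- dimnames(tpm) <- list(genes, ids)
  SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts, tpm = tpm),
    colData = S4Vectors::DataFrame(
      libraryId = ids,
      cleanTotal = vapply(tables, cleanTotal, 0),
      row.names = ids))
}
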