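# Generics, accessors and show methods for the package's S4 containers.
# Slot access from user code should go through these, never through @.

#' Library label of a tag container
#' @param x a RawTagLibrary, CleanTagTable, LibraryStats, ExpressionTable or
#'   MappingResult.
#' @return single character label.
#' @export
setGeneric("libraryId", function(x) standardGeneric("libraryId"))

#' @rdname libraryId
#' @export
setMethod("libraryId", "RawTagLibrary", function(x) x@libraryId)
#' @rdname libraryId
#' @export
setMethod("libraryId", "CleanTagTable", function(x) x@libraryId)
#' @rdname libraryId
#' @export
setMethod("libraryId", "LibraryStats", function(x) x@libraryId)
#' @rdname libraryId
#' @export
setMethod("libraryId", "ExpressionTable", function(x) x@libraryId)
#' @rdname libraryId
#' @export
setMethod("libraryId", "MappingResult", function(x) x@libraryId)

#' Tag copy numbers of a library
#' @param x a RawTagLibrary (returns the records data.frame) or a
#'   CleanTagTable (returns a named integer vector, tag -> copies).
#' @return see description.
#' @export
setGeneric("tagCounts", function(x) standardGeneric("tagCounts"))

#' @rdname tagCounts
#' @export
setMethod("tagCounts", "RawTagLibrary", function(x) x@records)
#' @rdname tagCounts
#' @export
setMethod("tagCounts", "CleanTagTable", function(x) x@counts)

#' Total clean tag copies of a library
#' @param x a CleanTagTable, LibraryStats or ExpressionTable.
#' @return single numeric total.
#' @export
setGeneric("cleanTotal", function(x) standardGeneric("cleanTotal"))

#' @rdname cleanTotal
#' @export
setMethod("cleanTotal", "CleanTagTable", function(x) sum(as.numeric(x@counts)))
#' @rdname cleanTotal
#' @export
setMethod("cleanTotal", "LibraryStats", function(x) x@cleanTotal)
#' @rdname cleanTotal
#' @export
setMethod("cleanTotal", "ExpressionTable", function(x) x@cleanTotal)

#' Per-gene unambiguous counts of a mapping result
#' @param x a MappingResult.
#' @return data.frame with columns gene, copies, distinctTags.
#' @export
setGeneric("geneCounts", function(x) standardGeneric("geneCounts"))

#' @rdname geneCounts
#' @export
setMethod("geneCounts", "MappingResult", function(x) x@geneCounts)

#' Aggregate mapping totals
#'
#' Named list with entries \code{cleanTotal}, \code{distinctClean},
#' \code{geneAllCopies}, \code{geneAllDistinct}, \code{geneUnambiguousCopies},
#' \code{geneUnambiguousDistinct}, \code{genomeCopies}, \code{genomeDistinct},
#' \code{unknownCopies}, \code{unknownDistinct}, \code{genesAll},
#' \code{genesUnambiguous}.
#'
#' @param x a MappingResult.
#' @return named list of counts.
#' @export
setGeneric("mappingTotals", function(x) standardGeneric("mappingTotals"))

#' @rdname mappingTotals
#' @export
setMethod("mappingTotals", "MappingResult", function(x) x@totals)

#' Tag sequences stored in a virtual tag index
#' @param x a VirtualTagIndex.
#' @return character vector of 21-nt tag sequences.
#' @export
setGeneric("indexTags", function(x) standardGeneric("indexTags"))

#' @rdname indexTags
#' @export
setMethod("indexTags", "VirtualTagIndex", function(x) x@tags)

#' @describeIn indexTags number of distinct tags in the index.
#' @export
setMethod("length", "VirtualTagIndex", function(x) length(x@tags))

#' TPM values of an expression table
#' @param x an ExpressionTable.
#' @return named numeric vector, gene -> TPM.
#' @export
setGeneric("tpmValues", function(x) standardGeneric("tpmValues"))

#' @rdname tpmValues
#' @export
setMethod("tpmValues", "ExpressionTable", function(x) {
  stats::setNames(x@tpm, x@gene)
})

#' Unambiguous tag copies of an expression table
#' @param x an ExpressionTable.
#' @return named numeric vector, gene -> copies.
#' @export
setGeneric("tagCopies", function(x) standardGeneric("tagCopies"))

#' @rdname tagCopies
#' @export
setMethod("tagCopies", "ExpressionTable", function(x) {
  stats::setNames(x@copies, x@gene)
})

#' Accessors for simulator ground truth
#'
#' @param x a SimTruth.
#' @return \code{trueExpression}: numeric matrix of expected relative
#'   abundances (gene x library; columns sum to 1); \code{deTruthLabels}:
#'   character matrix (up/down/null per gene and library pair);
#'   \code{tagProvenance}: list of per-library data.frames with one row per
#'   emitted raw tag.
#' @name simulationTruth
#' @export
setGeneric("trueExpression", function(x) standardGeneric("trueExpression"))

#' @rdname simulationTruth
#' @export
setMethod("trueExpression", "SimTruth", function(x) x@expression)

#' @rdname simulationTruth
#' @export
setGeneric("deTruthLabels", function(x) standardGeneric("deTruthLabels"))

#' @rdname simulationTruth
#' @export
setMethod("deTruthLabels", "SimTruth", function(x) x@deLabels)

#' @rdname simulationTruth
#' @export
setGeneric("tagProvenance", function(x) standardGeneric("tagProvenance"))

#' @rdname simulationTruth
#' @export
setMethod("tagProvenance", "SimTruth", function(x) x@provenance)

# ---- coercions ----

#' @export
setMethod("as.data.frame", "VirtualTagIndex", function(x, ...) {
  data.frame(
    tag = x@tags,
    gene_ids = vapply(x@geneIds, paste, "", collapse = ","),
    site_rank = x@siteRank,
    ambiguous = x@ambiguous,
    stringsAsFactors = FALSE
  )
})

#' @export
setMethod("as.data.frame", "ExpressionTable", function(x, ...) {
  data.frame(gene = x@gene, copies = x@copies, tpm = x@tpm,
             stringsAsFactors = FALSE)
})

#' @export
setMethod("as.data.frame", "LibraryStats", function(x, ...) {
  data.frame(
    metric = c("raw_total", "distinct_raw", "clean_total", "distinct_clean",
               "adaptor_only_copies", "n_contaminated_copies",
               "singleton_copies", "malformed_copies"),
    value = c(x@rawTotal, x@distinctRaw, x@cleanTotal, x@distinctClean,
              x@adaptorOnlyCopies, x@nContaminatedCopies,
              x@singletonCopies, x@malformedCopies),
    stringsAsFactors = FALSE
  )
})

# ---- show methods ----

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig:", object@nGenes, "genes,", object@nLibraries, "libraries, depth",
      object@depth, "\n")
  cat("  transcript length", paste(object@transcriptLengthRange, collapse = "-"),
      "nt, GC", object@gcContent, "\n")
  cat("  DE fraction", object@deFraction, "at fold", object@deFoldChange, "\n")
  cat("  error rate", object@errorRate, "| adaptor-only", object@adaptorOnlyRate,
      "| N-tag", object@nTagRate, "| seed", object@seed, "\n")
})

setMethod("show", "RawTagLibrary", function(object) {
  cat("RawTagLibrary", object@libraryId, ":", sum(object@records$count),
      "raw tag copies in", nrow(object@records), "records\n")
})

setMethod("show", "CleanTagTable", function(object) {
  cat("CleanTagTable", object@libraryId, ":", format(cleanTotal(object), big.mark = ","),
      "clean tag copies over", length(object@counts), "distinct tags\n")
})

setMethod("show", "LibraryStats", function(object) {
  cat("LibraryStats", object@libraryId, "\n")
  cat(sprintf("  raw %s (distinct %s) -> clean %s (distinct %s)\n",
              format(object@rawTotal, big.mark = ","),
              format(object@distinctRaw, big.mark = ","),
              format(object@cleanTotal, big.mark = ","),
              format(object@distinctClean, big.mark = ",")))
  pb <- object@pctBreakdown
  cat("  % of raw:", paste(sprintf("%s %.2f", names(pb), pb), collapse = ", "), "\n")
})

setMethod("show", "VirtualTagIndex", function(object) {
  cat("VirtualTagIndex:", length(object@tags), "distinct CATG+17-nt tags (",
      sum(object@ambiguous), "ambiguous );",
      length(object@genomeKmers), "genome 21-mers\n")
})

setMethod("show", "ExpressionTable", function(object) {
  cat("ExpressionTable", object@libraryId, ":", length(object@gene), "genes,",
      sum(object@copies > 0), "detected; clean total",
      format(object@cleanTotal, big.mark = ","), "\n")
})

setMethod("show", "MappingResult", function(object) {
  t <- object@totals
  cat("MappingResult", object@libraryId, "\n")
  cat(sprintf("  gene (all): %d copies / %d distinct; unambiguous: %d / %d\n",
              t$geneAllCopies, t$geneAllDistinct,
              t$geneUnambiguousCopies, t$geneUnambiguousDistinct))
  cat(sprintf("  genome: %d / %d; unknown: %d / %d; genes hit: %d (unambiguous %d)\n",
              t$genomeCopies, t$genomeDistinct, t$unknownCopies,
              t$unknownDistinct, t$genesAll, t$genesUnambiguous))
})

setMethod("show", "SimTruth", function(object) {
  cat("SimTruth:", nrow(object@expression), "genes x", ncol(object@expression),
      "libraries;", ncol(object@deLabels), "library pairs;",
      length(object@provenance), "provenance tables\n")
})

setMethod("show", "AnnotationSet", function(object) {
  cat("AnnotationSet:", length(object@terms), "terms over",
      length(object@universe), "annotated genes\n")
})
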