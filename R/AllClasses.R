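#' @import methods
NULL

#' Simulation configuration for the tag-sequencing protocol simulator
#'
#' Holds every tunable of the synthetic DGE experiment: transcriptome shape,
#' per-stage expression structure, sequencing depth and the protocol noise
#' rates. Construct with [simConfig()], which supplies defaults emulating a
#' desk-scale version of a three-stage pheromone-gland DGE experiment.
#'
#' @slot nGenes number of reference transcripts.
#' @slot transcriptLengthRange integer pair, min/max transcript length (nt).
#' @slot gcContent fraction of G+C in simulated transcripts.
#' @slot nLibraries number of stage libraries (default 3).
#' @slot baseMeanExpression expected transcripts per gene (scale of the
#'   log-normal abundance draw; relative abundances are normalized per library).
#' @slot deFraction fraction of genes differentially expressed between stages.
#' @slot deFoldChange fold change applied to DE genes (>= 1).
#' @slot depth raw tags drawn per library.
#' @slot errorRate per-base substitution probability over the 17-nt variable
#'   region of each sequenced tag.
#' @slot adaptorOnlyRate fraction of raw records that are adaptor-only (empty).
#' @slot nTagRate fraction of raw records containing an undetermined base N.
#' @slot seed integer seed; identical configurations reproduce byte-identical
#'   simulated experiments.
#' @seealso [simConfig()], [simulateDGEExperiment()]
#' @export
setClass("SimConfig",
  representation(
    nGenes = "integer",
    transcriptLengthRange = "integer",
    gcContent = "numeric",
    nLibraries = "integer",
    baseMeanExpression = "numeric",
    deFraction = "numeric",
    deFoldChange = "numeric",
    depth = "integer",
    errorRate = "numeric",
    adaptorOnlyRate = "numeric",
    nTagRate = "numeric",
    seed = "integer"
  )
)

setValidity("SimConfig", function(object) {
  msg <- character()
  if (object@nGenes < 1L) msg <- c(msg, "nGenes must be >= 1")
  r <- object@transcriptLengthRange
  if (length(r) != 2L || any(is.na(r))) msg <- c(msg, "transcriptLengthRange must be an integer pair")
  else {
    if (r[2L] < r[1L]) msg <- c(msg, "transcriptLengthRange: max < min")
    if (r[1L] < 25L) msg <- c(msg, "transcript lengths must be >= 25 nt (CATG + 17 nt + margin)")
  }
  if (object@gcContent < 0 || object@gcContent > 1) msg <- c(msg, "gcContent must be in [0,1]")
  if (object@nLibraries < 1L) msg <- c(msg, "nLibraries must be >= 1")
  if (object@baseMeanExpression <= 0) msg <- c(msg, "baseMeanExpression must be > 0")
  if (object@deFraction < 0 || object@deFraction > 1) msg <- c(msg, "deFraction must be in [0,1]")
  if (object@deFoldChange < 1) msg <- c(msg, "deFoldChange must be >= 1")
  if (object@depth < 1L) msg <- c(msg, "depth must be >= 1")
  if (object@errorRate < 0 || object@errorRate >= 1) msg <- c(msg, "errorRate must be in [0,1)")
  if (object@adaptorOnlyRate < 0 || object@adaptorOnlyRate >= 1) msg <- c(msg, "adaptorOnlyRate must be in [0,1)")
  if (object@nTagRate < 0 || object@nTagRate >= 1) msg <- c(msg, "nTagRate must be in [0,1)")
  if (object@adaptorOnlyRate + object@nTagRate >= 1) msg <- c(msg, "adaptorOnlyRate + nTagRate must be < 1")
  if (length(msg)) msg else TRUE
})

#' Ground truth of a simulated tag-sequencing experiment
#'
#' @slot expression gene x library matrix of expected relative abundances;
#'   each column sums to 1.
#' @slot deLabels gene x library-pair character matrix with entries
#'   \code{"up"}, \code{"down"} or \code{"null"} (orientation: later library
#'   over earlier library).
#' @slot provenance list with one data.frame per library
#'   (columns \code{class}, \code{gene}, \code{tag}); one row per emitted raw
#'   tag, \code{class} one of \code{gene}, \code{error_variant},
#'   \code{adaptor_only}, \code{n_contaminated}.
#' @export
setClass("SimTruth",
  representation(
    expression = "matrix",
    deLabels = "matrix",
    provenance = "list"
  )
)

setValidity("SimTruth", function(object) {
  msg <- character()
  cs <- colSums(object@expression)
  if (length(cs) && any(abs(cs - 1) > 1e-8))
    msg <- c(msg, "expression columns must each sum to 1")
  okLab <- all(object@deLabels %in% c("up", "down", "null"))
  if (!okLab) msg <- c(msg, "deLabels entries must be up/down/null")
  for (p in object@provenance) {
    if (!all(c("class", "gene", "tag") %in% names(p))) {
      msg <- c(msg, "each provenance table needs columns class, gene, tag")
      break
    }
    if (!all(p$class %in% c("gene", "error_variant", "adaptor_only", "n_contaminated"))) {
      msg <- c(msg, "unknown provenance class")
      break
    }
  }
  if (length(msg)) msg else TRUE
})

#' A raw tag library
#'
#' A multiset of sequenced 21-nt tag records with copy numbers, before any
#' cleaning. Adaptor-only (empty) artifact records are stored with an empty
#' string as the tag sequence; N-containing and malformed records keep their
#' sequence and are classified during cleaning.
#'
#' @slot libraryId label of the library (e.g. \code{"-72h"}).
#' @slot records data.frame with columns \code{tag} (character) and
#'   \code{count} (integer >= 1).
#' @seealso [cleanRawTags()], [readTagCounts()]
#' @export
setClass("RawTagLibrary",
  representation(libraryId = "character", records = "data.frame")
)

setValidity("RawTagLibrary", function(object) {
  msg <- character()
  rec <- object@records
  if (!all(c("tag", "count") %in% names(rec)))
    msg <- c(msg, "records must have columns 'tag' and 'count'")
  else {
    if (!is.character(rec$tag)) msg <- c(msg, "records$tag must be character")
    if (nrow(rec) && (any(is.na(rec$count)) || any(rec$count < 1) ||
        any(rec$count != floor(rec$count))))
      msg <- c(msg, "records$count must be integers >= 1")
  }
  if (length(object@libraryId) != 1L) msg <- c(msg, "libraryId must be a single label")
  if (length(msg)) msg else TRUE
})

#' A cleaned tag library
#'
#' Tag-to-copy-number map after removal of adaptor-only records, N-containing
#' tags, malformed tags and singletons. Every retained tag is a 21-nt
#' CATG-anchored sequence over A/C/G/T with copy number >= 2; the invariants
#' are enforced by the class validity.
#'
#' @slot libraryId label of the library.
#' @slot counts named integer vector, tag sequence -> copy number.
#' @export
setClass("CleanTagTable",
  representation(libraryId = "character", counts = "integer")
)

setValidity("CleanTagTable", function(object) {
  msg <- character()
  cnt <- object@counts
  tags <- names(cnt)
  if (length(cnt)) {
    if (is.null(tags) || anyDuplicated(tags)) msg <- c(msg, "counts must be uniquely named by tag")
    else {
      if (any(nchar(tags) != 21L)) msg <- c(msg, "all clean tags must be 21 nt")
      if (any(substr(tags, 1L, 4L) != "CATG")) msg <- c(msg, "all clean tags must begin with CATG")
      if (any(grepl("[^ACGT]", tags))) msg <- c(msg, "clean tags must be over {A,C,G,T}")
    }
    if (any(cnt < 2L)) msg <- c(msg, "all clean copy numbers must be >= 2")
  }
  if (length(object@libraryId) != 1L) msg <- c(msg, "libraryId must be a single label")
  if (length(msg)) msg else TRUE
})

#' Cleaning statistics of one raw library
#'
#' Copy-number bookkeeping of the cleaning filters, on both the total-tag and
#' distinct-tag bases, plus the percentage breakdown of raw tags by component
#' (clean / N-containing / adaptor-only / singleton / malformed), rounded
#' half-up to two decimals. The components of \code{pctBreakdown} sum to 100
#' up to rounding, and all copy buckets sum exactly to \code{rawTotal}.
#'
#' @slot libraryId label of the library.
#' @slot rawTotal total raw tag copies.
#' @slot distinctRaw distinct tag sequences among raw records (adaptor-only
#'   artifact records carry no sequence and are excluded).
#' @slot cleanTotal total clean tag copies.
#' @slot distinctClean distinct clean tags.
#' @slot adaptorOnlyCopies,nContaminatedCopies,singletonCopies,malformedCopies
#'   copies removed by each filter.
#' @slot pctBreakdown named numeric, percentages of \code{rawTotal}.
#' @export
setClass("LibraryStats",
  representation(
    libraryId = "character",
    rawTotal = "numeric",
    distinctRaw = "numeric",
    cleanTotal = "numeric",
    distinctClean = "numeric",
    adaptorOnlyCopies = "numeric",
    nContaminatedCopies = "numeric",
    singletonCopies = "numeric",
    malformedCopies = "numeric",
    pctBreakdown = "numeric"
  )
)

setValidity("LibraryStats", function(object) {
  msg <- character()
  tot <- object@cleanTotal + object@adaptorOnlyCopies + object@nContaminatedCopies +
    object@singletonCopies + object@malformedCopies
  if (!isTRUE(all.equal(tot, object@rawTotal)))
    msg <- c(msg, "component copies must sum to rawTotal")
  if (object@cleanTotal > object@rawTotal) msg <- c(msg, "cleanTotal must be <= rawTotal")
  if (length(msg)) msg else TRUE
})

#' Virtual tag reference index
#'
#' Every CATG+17-nt tag derivable from the reference transcripts, merged
#' across genes, with gene ownership, the site rank within the owning gene
#' (1 = 3'-most CATG site) and an ambiguity flag for tags shared by more than
#' one gene. Optionally carries a genome 21-mer set used as a secondary
#' reference for tags that do not match any gene.
#'
#' @slot tags character vector of unique 21-nt CATG-anchored tag sequences.
#' @slot geneIds list of character vectors, owning gene ids per tag.
#' @slot siteRank integer, smallest site rank of the tag among its owners.
#' @slot ambiguous logical, TRUE iff owned by more than one gene.
#' @slot genomeKmers character vector of genome-derived 21-mers (may be empty).
#' @seealso [buildTagIndex()], [mapTag()], [mapLibrary()]
#' @export
setClass("VirtualTagIndex",
  representation(
    tags = "character",
    geneIds = "list",
    siteRank = "integer",
    ambiguous = "logical",
    genomeKmers = "character"
  )
)

setValidity("VirtualTagIndex", function(object) {
  msg <- character()
  n <- length(object@tags)
  if (length(object@geneIds) != n || length(object@siteRank) != n ||
      length(object@ambiguous) != n)
    msg <- c(msg, "tags, geneIds, siteRank and ambiguous must be parallel")
  if (anyDuplicated(object@tags)) msg <- c(msg, "duplicate tag sequences in index")
  if (n) {
    if (any(nchar(object@tags) != 21L)) msg <- c(msg, "all index tags must be 21 nt")
    if (any(substr(object@tags, 1L, 4L) != "CATG")) msg <- c(msg, "all index tags must begin with CATG")
    amb <- lengths(object@geneIds) > 1L
    if (!identical(unname(amb), unname(object@ambiguous)))
      msg <- c(msg, "ambiguous flag must equal (number of owning genes > 1)")
  }
  if (length(msg)) msg else TRUE
})

#' Per-gene expression of one library
#'
#' Unambiguous tag copies per gene and the TPM normalization
#' \code{tpm = copies * 1e6 / cleanTotal} (transcripts per million clean
#' tags). Genes with zero mapped copies are retained with TPM 0.
#'
#' @slot libraryId label of the library.
#' @slot gene character vector of gene ids.
#' @slot copies numeric vector of unambiguous tag copies per gene.
#' @slot tpm numeric vector of TPM values.
#' @slot cleanTotal total clean tags of the library (TPM denominator).
#' @seealso [computeTPM()], [callDEGenes()]
#' @export
setClass("ExpressionTable",
  representation(
    libraryId = "character",
    gene = "character",
    copies = "numeric",
    tpm = "numeric",
    cleanTotal = "numeric"
  )
)

setValidity("ExpressionTable", function(object) {
  msg <- character()
  n <- length(object@gene)
  if (length(object@copies) != n || length(object@tpm) != n)
    msg <- c(msg, "gene, copies and tpm must be parallel")
  if (anyDuplicated(object@gene)) msg <- c(msg, "duplicate gene ids")
  if (object@cleanTotal <= 0) msg <- c(msg, "cleanTotal must be > 0")
  if (n && any(object@copies < 0)) msg <- c(msg, "copies must be >= 0")
  if (n) {
    expect <- object@copies * 1e6 / object@cleanTotal
    if (max(abs(expect - object@tpm)) > 1e-6 * max(1, max(expect)))
      msg <- c(msg, "tpm must equal copies * 1e6 / cleanTotal")
  }
  if (length(msg)) msg else TRUE
})

#' Result of mapping one clean library against the virtual tag index
#'
#' Per-tag categories (\code{gene_unambiguous}, \code{gene_ambiguous},
#' \code{genome}, \code{unknown}; the first two together are the
#' "all tags mapping to gene" class), per-gene unambiguous tag counts and the
#' aggregate totals on both total-copy and distinct-tag bases. Categories
#' partition the clean tag set (gene > genome > unknown precedence).
#'
#' @slot libraryId label of the library.
#' @slot perTag data.frame with columns \code{tag}, \code{count},
#'   \code{category}, \code{genes} (comma-joined owners at best distance) and
#'   \code{mismatch} (0, 1 or NA).
#' @slot geneCounts data.frame with columns \code{gene}, \code{copies},
#'   \code{distinctTags} (unambiguous mapping only).
#' @slot totals named list of aggregate counts (see [mappingTotals()]).
#' @export
setClass("MappingResult",
  representation(
    libraryId = "character",
    perTag = "data.frame",
    geneCounts = "data.frame",
    totals = "list"
  )
)

setValidity("MappingResult", function(object) {
  msg <- character()
  pt <- object@perTag
  if (nrow(pt)) {
    if (!all(pt$category %in% c("gene_unambiguous", "gene_ambiguous", "genome", "unknown")))
      msg <- c(msg, "unknown mapping category")
    tot <- object@totals
    part <- tot$geneAllCopies + tot$genomeCopies + tot$unknownCopies
    if (part != tot$cleanTotal)
      msg <- c(msg, "gene_all + genome + unknown copies must equal cleanTotal")
    if (tot$geneUnambiguousCopies > tot$geneAllCopies)
      msg <- c(msg, "unambiguous copies cannot exceed all gene-mapped copies")
    if (nrow(object@geneCounts) &&
        sum(object@geneCounts$copies) != tot$geneUnambiguousCopies)
      msg <- c(msg, "per-gene copies must sum to the unambiguous total")
  }
  if (length(msg)) msg else TRUE
})

#' Term annotation set for enrichment analysis
#'
#' Gene-to-term annotation (GO/KO ids treated as opaque labels) with the
#' background universe defined as every gene carrying at least one
#' annotation.
#'
#' @slot terms named list, term id -> character vector of annotated genes.
#' @slot universe character vector of genes with any annotation.
#' @seealso [annotationSet()], [enrichAllTerms()]
#' @export
setClass("AnnotationSet",
  representation(terms = "list", universe = "character")
)

setValidity("AnnotationSet", function(object) {
  msg <- character()
  if (length(object@terms) == 0L) msg <- c(msg, "annotation must contain at least one term")
  if (any(lengths(object@terms) == 0L)) msg <- c(msg, "terms must be nonempty")
  if (is.null(names(object@terms)) || anyDuplicated(names(object@terms)))
    msg <- c(msg, "terms must be uniquely named")
  allg <- unique(unlist(object@terms, use.names = FALSE))
  if (!all(allg %in% object@universe))
    msg <- c(msg, "every annotated gene must be in the universe")
  if (length(msg)) msg else TRUE
})
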