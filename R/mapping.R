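# Tag-to-reference mapping with <= 1 mismatch and category classification.

# Internal vectorized classifier. For each query tag: exact hits beat
# one-mismatch hits (best-distance rule); ambiguity is judged on the union of
# owning genes within the best distance stratum only. Tags mapping to no gene
# are checked (<= 1 mismatch) against the genome 21-mer set, the rest are
# unknown. Returns data.frame(tag, category, genes, mismatch).
.classifyTags <- function(tags, index) {
  n <- length(tags)
  category <- rep.int("unknown", n)
  genes <- rep.int("", n)
  mismatch <- rep(NA_integer_, n)
  if (!n) return(data.frame(tag = tags, category = category, genes = genes,
                            mismatch = mismatch, stringsAsFactors = FALSE))

  exact <- match(tags, index@tags)
  hitE <- !is.na(exact)
  if (any(hitE)) {
    gl <- index@geneIds[exact[hitE]]
    category[hitE] <- ifelse(lengths(gl) == 1L, "gene_unambiguous", "gene_ambiguous")
    genes[hitE] <- vapply(gl, function(g) paste(sort(g), collapse = ","), "")
    mismatch[hitE] <- 0L
  }

  todo <- which(!hitE)
  if (length(todo)) {
    nb <- .tagNeighborhood(tags[todo])
    hits <- match(nb$variant, index@tags)
    ok <- !is.na(hits)
    if (any(ok)) {
      byQuery <- split(hits[ok], nb$query[ok])
      qIdx <- todo[as.integer(names(byQuery))]
      gl <- lapply(byQuery, function(rows)
        unique(unlist(index@geneIds[unique(rows)], use.names = FALSE)))
      category[qIdx] <- ifelse(lengths(gl) == 1L, "gene_unambiguous", "gene_ambiguous")
      genes[qIdx] <- vapply(gl, function(g) paste(sort(g), collapse = ","), "")
      mismatch[qIdx] <- 1L
    }
  }

  if (length(index@genomeKmers)) {
    left <- which(category == "unknown")
    if (length(left)) {
      gE <- !is.na(match(tags[left], index@genomeKmers))
      category[left[gE]] <- "genome"
      mismatch[left[gE]] <- 0L
      rest <- left[!gE]
      if (length(rest)) {
        nb <- .tagNeighborhood(tags[rest])
        gh <- !is.na(match(nb$variant, index@genomeKmers))
        if (any(gh)) {
          qIdx <- rest[unique(nb$query[gh])]
          category[qIdx] <- "genome"
          mismatch[qIdx] <- 1L
        }
      }
    }
  }
  data.frame(tag = tags, category = category, genes = genes,
             mismatch = mismatch, stringsAsFactors = FALSE)
}

#' Map a single clean tag against the virtual tag index
#'
#' Exact matches take precedence over one-mismatch matches (mismatches are
#' counted over the 17-nt variable region; the CATG anchor is fixed). Within
#' the best distance stratum the tag is \code{gene_unambiguous} if the union
#' of owning genes is a single gene, \code{gene_ambiguous} otherwise. A tag
#' matching no gene is \code{genome} if it matches the genome 21-mer set
#' within one mismatch (gene > genome precedence), else \code{unknown}.
#'
#' @param tag a 21-nt CATG-anchored tag over A/C/G/T.
#' @param index a [VirtualTagIndex-class].
#' @return list with \code{category}, \code{geneIds} (character, possibly
#'   empty) and \code{mismatches} (0, 1 or NA for unmatched).
#' @export
mapTag <- function(tag, index) {
  stopifnot(length(tag) == 1L, is(index, "VirtualTagIndex"))
  if (nchar(tag) != 21L || substr(tag, 1L, 4L) != "CATG" || grepl("[^ACGT]", tag))
    stop("'tag' must be a 21-nt CATG-anchored sequence over {A,C,G,T}")
  row <- .classifyTags(tag, index)
  gid <- if (nzchar(row$genes)) strsplit(row$genes, ",", fixed = TRUE)[[1L]]
         else character()
  list(category = row$category, geneIds = gid, mismatches = row$mismatch)
}

#' Map a clean library against the virtual tag index
#'
#' Classifies every distinct clean tag with [mapTag()] semantics, aggregates
#' copies by category, and tallies per-gene unambiguous tag counts (a tag
#' hitting several sites of the same gene counts once toward that gene).
#' Category totals are reported on both the total-copy and distinct-tag
#' bases, together with tag-mapped gene counts (all vs unambiguous).
#'
#' @param clean a [CleanTagTable-class].
#' @param index a nonempty [VirtualTagIndex-class].
#' @return a [MappingResult-class].
#' @export
mapLibrary <- function(clean, index) {
  stopifnot(is(clean, "CleanTagTable"), is(index, "VirtualTagIndex"))
  if (length(index) == 0L) stop("'index' is empty")
  counts <- clean@counts
  tags <- names(counts)
  perTag <- .classifyTags(tags, index)
  perTag$count <- as.integer(counts)
  perTag <- perTag[, c("tag", "count", "category", "genes", "mismatch")]

  isGene <- perTag$category %in% c("gene_unambiguous", "gene_ambiguous")
  isUn <- perTag$category == "gene_unambiguous"
  isGenome <- perTag$category == "genome"
  isUnknown <- perTag$category == "unknown"

  geneCounts <- if (any(isUn)) {
    g <- perTag$genes[isUn]
    agg <- data.frame(gene = g, copies = perTag$count[isUn])
    copies <- tapply(agg$copies, agg$gene, sum)
    distinct <- tapply(agg$copies, agg$gene, length)
    data.frame(gene = names(copies), copies = as.numeric(copies),
               distinctTags = as.integer(distinct), stringsAsFactors = FALSE,
               row.names = NULL)
  } else {
    data.frame(gene = character(), copies = numeric(),
               distinctTags = integer(), stringsAsFactors = FALSE)
  }

  allGenes <- unique(unlist(strsplit(perTag$genes[isGene], ",", fixed = TRUE),
                            use.names = FALSE))
  totals <- list(
    cleanTotal = sum(perTag$count),
    distinctClean = nrow(perTag),
    geneAllCopies = sum(perTag$count[isGene]),
    geneAllDistinct = sum(isGene),
    geneUnambiguousCopies = sum(perTag$count[isUn]),
    geneUnambiguousDistinct = sum(isUn),
    genomeCopies = sum(perTag$count[isGenome]),
    genomeDistinct = sum(isGenome),
    unknownCopies = sum(perTag$count[isUnknown]),
    unknownDistinct = sum(isUnknown),
    genesAll = length(allGenes),
    genesUnambiguous = nrow(geneCounts)
  )
  new("MappingResult", libraryId = clean@libraryId, perTag = perTag,
      geneCounts = geneCounts, totals = totals)
}
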