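# Raw-library cleaning and library-statistics reporting.

#' Clean a raw tag library
#'
#' Applies the standard tag-library filters in order: adaptor-only (empty)
#' records, then reads containing an undetermined base N, then structurally
#' malformed reads (length != 21, missing CATG anchor, or non-ACGT
#' characters), and finally tags whose total copy number after the first
#' filters is 1 (singletons, overwhelmingly sequencing-error variants).
#' Singleton status is judged on aggregated sequence counts, never on
#' artifact records. Nothing is silently dropped: every removed copy lands in
#' one of the statistics buckets and the buckets sum exactly to the raw
#' total.
#'
#' @param raw a [RawTagLibrary-class].
#' @return list with \code{clean} (a [CleanTagTable-class]) and \code{stats}
#'   (a [LibraryStats-class]).
#' @export
#' @examples
#' raw <- new("RawTagLibrary", libraryId = "demo",
#'            records = data.frame(
#'              tag = c("", "CATGACGTACGTACGTACGTA", "CATGNCGTACGTACGTACGTA",
#'                      "CATGTTTTACGTACGTACGTA"),
#'              count = c(1L, 3L, 2L, 1L)))
#' res <- cleanRawTags(raw)
#' tagCounts(res$clean)   # only the copy-3 tag survives
#' res$stats
cleanRawTags <- function(raw) {
  stopifnot(is(raw, "RawTagLibrary"))
  rec <- raw@records
  tag <- rec$tag
  count <- as.numeric(rec$count)
  rawTotal <- sum(count)

  adaptor <- is.na(tag) | tag == ""
  ncont <- !adaptor & grepl("N", tag, fixed = TRUE)
  malformed <- !adaptor & !ncont &
    (nchar(tag) != 21L | substr(tag, 1L, 4L) != "CATG" | grepl("[^ACGT]", tag))
  keep <- !(adaptor | ncont | malformed)

  distinctRaw <- length(unique(tag[!adaptor]))

  # aggregate surviving sequences before judging singletons: the same tag may
  # appear in several records of a shuffled input
  agg <- tapply(count[keep], factor(tag[keep], levels = unique(tag[keep])), sum)
  aggTags <- names(agg)
  agg <- as.numeric(agg)
  single <- agg == 1
  cleanCounts <- as.integer(agg[!single])
  names(cleanCounts) <- aggTags[!single]
  if (length(cleanCounts)) cleanCounts <- cleanCounts[order(names(cleanCounts))]

  cleanTotalN <- sum(as.numeric(cleanCounts))
  adCopies <- sum(count[adaptor])
  nCopies <- sum(count[ncont])
  malCopies <- sum(count[malformed])
  singleCopies <- sum(agg[single])

  pct <- c(
    clean = percentOf(cleanTotalN, rawTotal),
    n_contaminated = percentOf(nCopies, rawTotal),
    adaptor_only = percentOf(adCopies, rawTotal),
    singleton = percentOf(singleCopies, rawTotal),
    malformed = percentOf(malCopies, rawTotal)
  )
  if (rawTotal == 0) pct[] <- 0

  clean <- new("CleanTagTable", libraryId = raw@libraryId, counts = cleanCounts)
  stats <- new("LibraryStats",
    libraryId = raw@libraryId,
    rawTotal = rawTotal,
    distinctRaw = distinctRaw,
    cleanTotal = cleanTotalN,
    distinctClean = length(cleanCounts),
    adaptorOnlyCopies = adCopies,
    nContaminatedCopies = nCopies,
    singletonCopies = singleCopies,
    malformedCopies = malCopies,
    pctBreakdown = pct
  )
  list(clean = clean, stats = stats)
}

#' Render library-statistics percentages
#'
#' Produces the conventional statistics block of a tag-sequencing report:
#' clean tags as a percentage of raw tags, and each mapping category as a
#' percentage of clean tags (total basis), of distinct clean tags (distinct
#' basis) or of reference genes, all rounded half-up to two decimals. A zero
#' denominator yields \code{NA} (an undefined ratio), never 0.
#'
#' @param counts named list or vector of counts. Recognized names:
#'   \code{rawTotal}, \code{distinctRaw}, \code{cleanTotal},
#'   \code{distinctClean}, \code{geneAllCopies}, \code{geneAllDistinct},
#'   \code{geneUnambiguousCopies}, \code{geneUnambiguousDistinct},
#'   \code{genomeCopies}, \code{genomeDistinct}, \code{unknownCopies},
#'   \code{unknownDistinct}, \code{genesAll}, \code{genesUnambiguous},
#'   \code{nRefGenes}. Only supplied entries are reported.
#' @return data.frame with columns \code{metric}, \code{count},
#'   \code{percent} and \code{percent_of} (the denominator used).
#' @export
#' @examples
#' summarizeLibrary(list(rawTotal = 6137521, cleanTotal = 6037779,
#'                       geneAllCopies = 1381410))
summarizeLibrary <- function(counts) {
  counts <- as.list(counts)
  gv <- function(nm) if (!is.null(counts[[nm]])) as.numeric(counts[[nm]]) else NA_real_
  raw <- gv("rawTotal"); clean <- gv("cleanTotal")
  dclean <- gv("distinctClean"); nref <- gv("nRefGenes")
  rows <- list(
    list("raw_total",                 raw,                        NA_real_, ""),
    list("distinct_raw",              gv("distinctRaw"),          NA_real_, ""),
    list("clean_total",               clean,                      raw,      "raw"),
    list("distinct_clean",            dclean,                     NA_real_, ""),
    list("gene_all",                  gv("geneAllCopies"),        clean,    "clean"),
    list("distinct_gene_all",         gv("geneAllDistinct"),      dclean,   "distinct_clean"),
    list("gene_unambiguous",          gv("geneUnambiguousCopies"), clean,   "clean"),
    list("distinct_gene_unambiguous", gv("geneUnambiguousDistinct"), dclean, "distinct_clean"),
    list("genes_all",                 gv("genesAll"),             nref,     "ref_genes"),
    list("genes_unambiguous",         gv("genesUnambiguous"),     nref,     "ref_genes"),
    list("genome",                    gv("genomeCopies"),         clean,    "clean"),
    list("distinct_genome",           gv("genomeDistinct"),       dclean,   "distinct_clean"),
    list("unknown",                   gv("unknownCopies"),        clean,    "clean"),
    list("distinct_unknown",          gv("unknownDistinct"),      dclean,   "distinct_clean")
  )
  keep <- vapply(rows, function(r) !is.na(r[[2]]), TRUE)
  rows <- rows[keep]
  pct <- vapply(rows, function(r) {
    den <- r[[3]]
    if (is.na(den)) NA_real_ else percentOf(r[[2]], den)
  }, 0)
  data.frame(
    metric = vapply(rows, `[[`, "", 1L),
    count = vapply(rows, `[[`, 0, 2L),
    percent = pct,
    percent_of = vapply(rows, `[[`, "", 4L),
    stringsAsFactors = FALSE
  )
}
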