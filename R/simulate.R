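# Protocol simulator: reference transcriptomes, stage-wise expression
# profiles and raw tag libraries with full per-tag ground truth.
#
# The simulated protocol mirrors NlaIII/MmeI tag sequencing: transcripts are
# anchored at CATG sites, a sequenced tag is the 3'-most CATG plus the 17 nt
# released by the MmeI cut, and libraries are contaminated with adaptor-only
# records and N-containing reads at configurable rates. Substitution errors
# hit only the 17-nt variable region: a corrupted CATG anchor would not be
# recognized as a tag at all, so such molecules never enter a raw library.

#' Build a simulation configuration
#'
#' Defaults describe a desk-scale three-stage DGE experiment: 2000 genes,
#' half a million raw tags per library, a 10\% DE fraction at 4-fold change,
#' and protocol noise chosen to reproduce the composition of real raw tag
#' libraries, where clean tags are about 98\% of raw tags: a 0.1\% per-base
#' substitution error over the 17-nt variable region (so about 1.7\% of tags
#' carry an error and are overwhelmingly removed as singletons) and 0.5\%
#' each of adaptor-only and N-containing records.
#'
#' @param nGenes number of reference transcripts.
#' @param transcriptLengthRange integer pair of min/max transcript length (nt,
#'   min >= 25).
#' @param gcContent G+C fraction of simulated transcripts.
#' @param nLibraries number of stage libraries.
#' @param baseMeanExpression expected transcripts per gene (scale of the
#'   log-normal abundance draw).
#' @param deFraction fraction of genes differentially expressed.
#' @param deFoldChange fold change of DE genes (>= 1).
#' @param depth raw tags per library.
#' @param errorRate per-base substitution probability over the 17-nt variable
#'   region.
#' @param adaptorOnlyRate fraction of raw records that are adaptor-only.
#' @param nTagRate fraction of raw records containing an N.
#' @param seed integer seed (< 2^31); the whole simulated experiment is a
#'   deterministic function of the configuration.
#' @return a validated [SimConfig-class] object.
#' @export
#' @examples
#' cfg <- simConfig(nGenes = 50, depth = 1000L, seed = 7)
#' cfg
simConfig <- function(nGenes = 2000L,
                      transcriptLengthRange = c(300L, 2000L),
                      gcContent = 0.4,
                      nLibraries = 3L,
                      baseMeanExpression = 250,
                      deFraction = 0.1,
                      deFoldChange = 4,
                      depth = 500000L,
                      errorRate = 0.001,
                      adaptorOnlyRate = 0.005,
                      nTagRate = 0.005,
                      seed = 1L) {
  new("SimConfig",
    nGenes = as.integer(nGenes),
    transcriptLengthRange = as.integer(transcriptLengthRange),
    gcContent = as.numeric(gcContent),
    nLibraries = as.integer(nLibraries),
    baseMeanExpression = as.numeric(baseMeanExpression),
    deFraction = as.numeric(deFraction),
    deFoldChange = as.numeric(deFoldChange),
    depth = as.integer(depth),
    errorRate = as.numeric(errorRate),
    adaptorOnlyRate = as.numeric(adaptorOnlyRate),
    nTagRate = as.numeric(nTagRate),
    seed = as.integer(seed)
  )
}

#' Simulate a reference transcriptome
#'
#' Draws \code{nGenes} i.i.d. transcripts with uniform lengths in
#' \code{transcriptLengthRange} and independent bases at the configured GC
#' content. Each sequence carries a \code{taggable} flag in its metadata
#' columns: whether it contains at least one CATG site with >= 17 nt
#' downstream, i.e. whether the tag protocol can observe it at all.
#'
#' @param config a [SimConfig-class].
#' @return a [Biostrings::DNAStringSet] named \code{gene0001, ...} with
#'   \code{mcols(x)$taggable}.
#' @export
#' @examples
#' genes <- simulateTranscriptome(simConfig(nGenes = 5, seed = 1))
#' S4Vectors::mcols(genes)$taggable
simulateTranscriptome <- function(config) {
  validObject(config)
  set.seed(config@seed)
  n <- config@nGenes
  r <- config@transcriptLengthRange
  lens <- r[1L] + sample.int(r[2L] - r[1L] + 1L, n, replace = TRUE) - 1L
  gc <- config@gcContent
  probs <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  chars <- sample(.DNA_BASES, sum(lens), replace = TRUE, prob = probs)
  seqs <- vapply(split(chars, factor(rep.int(seq_len(n), lens), levels = seq_len(n))),
                 paste, "", collapse = "")
  names(seqs) <- sprintf("gene%0*d", max(4L, nchar(n)), seq_len(n))
  out <- Biostrings::DNAStringSet(seqs)
  pos <- gregexpr("CATG", seqs, fixed = TRUE)
  taggable <- mapply(function(p, L) any(p > 0L & p + 20L <= L), pos, lens,
                     USE.NAMES = FALSE)
  S4Vectors::mcols(out)$taggable <- taggable
  out
}

#' Simulate stage-wise expression profiles with DE structure
#'
#' Base relative abundances are log-normal (unit log-sd) around
#' \code{baseMeanExpression}. A \code{deFraction} of genes (Bernoulli per
#' gene) is differentially expressed: each DE gene picks a change-point stage
#' uniformly among libraries 2..n and is multiplied by
#' \code{deFoldChange} (up) or \code{1/deFoldChange} (down, equiprobable)
#' from that stage onward. Columns are normalized to sum to 1.
#'
#' @param config a [SimConfig-class]; \code{nLibraries >= 2} is required for
#'   any DE structure.
#' @param genes a named [Biostrings::DNAStringSet] or named character vector
#'   (only the names and count are used).
#' @return list with \code{expression} (gene x library matrix, columns
#'   summing to 1), \code{deLabels} (gene x pair character matrix, columns
#'   \code{"libi_vs_libj"}, orientation later over earlier), \code{isDE},
#'   \code{direction} (\code{"up"}/\code{"down"}/\code{NA}) and
#'   \code{changePoint}.
#' @export
simulateExpressionProfiles <- function(config, genes) {
  validObject(config)
  nLib <- config@nLibraries
  if (config@deFraction > 0 && nLib < 2L)
    stop("at least 2 libraries are required for differential expression structure")
  n <- length(genes)
  ids <- names(genes)
  if (is.null(ids)) stop("'genes' must be named by gene id")
  set.seed(config@seed + 1L)
  w <- stats::rlnorm(n, meanlog = log(config@baseMeanExpression), sdlog = 1)
  isDE <- stats::runif(n) < config@deFraction
  dirUp <- sample(c(TRUE, FALSE), n, replace = TRUE)
  changePoint <- if (nLib >= 2L) 1L + sample.int(nLib - 1L, n, replace = TRUE)
                 else rep(NA_integer_, n)
  fold <- config@deFoldChange
  mult <- ifelse(dirUp, fold, 1 / fold)
  expr <- matrix(w, nrow = n, ncol = nLib,
                 dimnames = list(ids, paste0("lib", seq_len(nLib))))
  for (l in seq_len(nLib)) {
    hit <- isDE & !is.na(changePoint) & changePoint <= l
    expr[hit, l] <- expr[hit, l] * mult[hit]
  }
  expr <- sweep(expr, 2L, colSums(expr), "/")
  pairs <- if (nLib >= 2L) utils::combn(nLib, 2L) else matrix(integer(), 2L, 0L)
  deLabels <- matrix("null", nrow = n, ncol = ncol(pairs),
                     dimnames = list(ids, apply(pairs, 2L, function(p)
                       sprintf("lib%d_vs_lib%d", p[1L], p[2L]))))
  for (k in seq_len(ncol(pairs))) {
    i <- pairs[1L, k]; j <- pairs[2L, k]
    crossing <- isDE & !is.na(changePoint) & changePoint > i & changePoint <= j
    deLabels[crossing, k] <- ifelse(dirUp[crossing], "up", "down")
  }
  list(expression = expr, deLabels = deLabels, isDE = isDE,
       direction = ifelse(isDE, ifelse(dirUp, "up", "down"), NA_character_),
       changePoint = ifelse(isDE, changePoint, NA_integer_))
}

# 3'-most CATG+17-nt tag of each sequence, NA where no site qualifies
.threePrimeTags <- function(seqs) {
  pos <- gregexpr("CATG", seqs, fixed = TRUE)
  lens <- nchar(seqs)
  vapply(seq_along(seqs), function(i) {
    p <- pos[[i]]
    p <- p[p > 0L & p + 20L <= lens[i]]
    if (!length(p)) return(NA_character_)
    p3 <- max(p)
    tag <- substr(seqs[i], p3, p3 + 20L)
    if (grepl("[^ACGT]", tag)) NA_character_ else tag
  }, "")
}

# apply nmut substitutions in the 17-nt variable region of each tag
.mutateTags <- function(tags, nmut) {
  if (!length(tags)) return(tags)
  mat <- matrix(unlist(strsplit(tags, "", fixed = TRUE), use.names = FALSE),
                nrow = length(tags), byrow = TRUE)
  for (i in seq_along(tags)) {
    for (p in 4L + sample.int(17L, nmut[i])) {
      mat[i, p] <- sample(setdiff(.DNA_BASES, mat[i, p]), 1L)
    }
  }
  do.call(paste0, as.data.frame(mat, stringsAsFactors = FALSE))
}

# a CATG-anchored 21-nt read with >= 1 undetermined base in the variable region
.makeNTags <- function(k) {
  if (!k) return(character())
  body <- matrix(sample(.DNA_BASES, 17L * k, replace = TRUE), nrow = k)
  npos <- sample.int(17L, k, replace = TRUE)
  body[cbind(seq_len(k), npos)] <- "N"
  paste0("CATG", do.call(paste0, as.data.frame(body, stringsAsFactors = FALSE)))
}

#' Simulate raw tag libraries with per-tag provenance
#'
#' For each library, \code{depth} raw records are drawn: an adaptor-only
#' (empty) artifact with probability \code{adaptorOnlyRate}, an N-containing
#' read with probability \code{nTagRate}, otherwise a gene is sampled
#' proportional to its expected abundance among taggable genes (a transcript
#' without a usable CATG site yields no NlaIII fragment and cannot contribute
#' sequencing depth), its 3'-most CATG+17-nt tag is emitted, and independent
#' per-base substitution errors at \code{errorRate} are applied over the
#' 17-nt variable region. Every emitted record gets exactly one provenance
#' row, so filter and mapping results can be reconciled against the truth.
#'
#' @param config a [SimConfig-class].
#' @param genes named DNAStringSet or character vector of transcripts.
#' @param profiles the list returned by [simulateExpressionProfiles()] (its
#'   \code{expression} matrix and \code{deLabels} feed the ground truth).
#' @return list with \code{libraries} (list of [RawTagLibrary-class], one per
#'   library) and \code{truth} (a [SimTruth-class]).
#' @export
simulateRawTags <- function(config, genes, profiles) {
  validObject(config)
  seqs <- .asNamedSeqs(genes)
  ids <- names(seqs)
  expr <- profiles$expression
  if (!identical(rownames(expr), ids))
    stop("expression matrix rows must match the gene set")
  vt <- .threePrimeTags(seqs)
  taggable <- !is.na(vt)
  if (!any(taggable))
    stop("simulation error: no taggable gene (no CATG site with 17 nt downstream) ",
         "with nonzero abundance in the reference")
  set.seed(config@seed + 2L)
  nLib <- config@nLibraries
  libs <- vector("list", nLib)
  prov <- vector("list", nLib)
  for (l in seq_len(nLib)) {
    libId <- paste0("lib", l)
    classCounts <- stats::rmultinom(1L, config@depth,
      c(config@adaptorOnlyRate, config@nTagRate,
        1 - config@adaptorOnlyRate - config@nTagRate))[, 1L]
    nAd <- classCounts[1L]; nN <- classCounts[2L]; nG <- classCounts[3L]
    ab <- expr[taggable, l]
    if (sum(ab) <= 0)
      stop("simulation error: taggable genes have zero total abundance in ", libId)
    gCounts <- stats::rmultinom(1L, nG, ab / sum(ab))[, 1L]
    geneVec <- rep.int(ids[taggable], gCounts)
    tagVec <- rep.int(vt[taggable], gCounts)
    nmut <- stats::rbinom(length(tagVec), 17L, config@errorRate)
    mut <- nmut > 0L
    if (any(mut)) tagVec[mut] <- .mutateTags(tagVec[mut], nmut[mut])
    nTagSeqs <- .makeNTags(nN)
    provDf <- data.frame(
      class = c(rep.int("adaptor_only", nAd), rep.int("n_contaminated", nN),
                ifelse(mut, "error_variant", "gene")),
      gene = c(rep.int(NA_character_, nAd + nN), geneVec),
      tag = c(rep.int("", nAd), nTagSeqs, tagVec),
      stringsAsFactors = FALSE
    )
    prov[[l]] <- provDf
    cnt <- table(provDf$tag)
    libs[[l]] <- new("RawTagLibrary", libraryId = libId,
                     records = data.frame(tag = names(cnt),
                                          count = as.integer(cnt),
                                          stringsAsFactors = FALSE))
  }
  names(libs) <- vapply(libs, libraryId, "")
  names(prov) <- names(libs)
  truth <- new("SimTruth", expression = expr, deLabels = profiles$deLabels,
               provenance = prov)
  list(libraries = libs, truth = truth)
}

#' Simulate a complete tag-sequencing experiment
#'
#' Convenience composition of [simulateTranscriptome()],
#' [simulateExpressionProfiles()] and [simulateRawTags()].
#'
#' @param config a [SimConfig-class].
#' @return list with \code{config}, \code{genes}, \code{profiles},
#'   \code{libraries} and \code{truth}.
#' @export
#' @examples
#' sim <- simulateDGEExperiment(simConfig(nGenes = 30, depth = 2000L,
#'                                        nLibraries = 2L, seed = 3))
#' sim$libraries[[1]]
simulateDGEExperiment <- function(config) {
  genes <- simulateTranscriptome(config)
  profiles <- simulateExpressionProfiles(config, genes)
  raw <- simulateRawTags(config, genes, profiles)
  list(config = config, genes = genes, profiles = profiles,
       libraries = raw$libraries, truth = raw$truth)
}
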