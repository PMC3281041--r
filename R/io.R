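# Plain-text I/O: FASTA/FASTQ via Biostrings, tag-count and annotation TSVs.

#' Read a reference transcriptome FASTA
#' @param path FASTA file (gene id in the header).
#' @return named [Biostrings::DNAStringSet].
#' @export
readReferenceFasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  names(x) <- sub("\\s.*$", "", names(x))
  x
}

#' Write a reference transcriptome FASTA
#' @param genes named DNAStringSet or named character vector.
#' @param path output file.
#' @return invisibly, the path.
#' @export
writeReferenceFasta <- function(genes, path) {
  if (!is(genes, "DNAStringSet")) genes <- Biostrings::DNAStringSet(genes)
  Biostrings::writeXStringSet(genes, filepath = path)
  invisible(path)
}

#' Read a raw library from a tag-count TSV
#'
#' Two tab-separated columns \code{tag} and \code{count}; an empty tag field
#' denotes an adaptor-only artifact record.
#'
#' @param path TSV file.
#' @param libraryId label for the library (default: file name without
#'   extension).
#' @return a [RawTagLibrary-class].
#' @export
readTagCounts <- function(path, libraryId = sub("\\.[^.]*$", "", basename(path))) {
  df <- utils::read.delim(path, header = TRUE, quote = "",
                          colClasses = c("character", "integer"),
                          na.strings = character())
  names(df) <- c("tag", "count")
  new("RawTagLibrary", libraryId = libraryId, records = df)
}

#' Write a raw library or clean table as a tag-count TSV
#' @param x a [RawTagLibrary-class] or [CleanTagTable-class].
#' @param path output TSV.
#' @return invisibly, the path.
#' @export
writeTagCounts <- function(x, path) {
  df <- if (is(x, "RawTagLibrary")) x@records
        else if (is(x, "CleanTagTable"))
          data.frame(tag = names(x@counts), count = unname(x@counts),
                     stringsAsFactors = FALSE)
        else stop("'x' must be a RawTagLibrary or CleanTagTable")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a cleaned library from a tag-count TSV
#' @param path TSV with columns tag, count (all tags must satisfy the
#'   clean-tag invariants).
#' @param libraryId label for the library.
#' @return a [CleanTagTable-class].
#' @export
readCleanTags <- function(path, libraryId = sub("\\.[^.]*$", "", basename(path))) {
  df <- utils::read.delim(path, header = TRUE, quote = "",
                          colClasses = c("character", "integer"),
                          na.strings = character())
  new("CleanTagTable", libraryId = libraryId,
      counts = stats::setNames(as.integer(df[[2L]]), df[[1L]]))
}

#' Write a raw library as FASTQ
#'
#' One read per tag copy, fixed quality \code{I}. Adaptor-only artifact
#' records have no tag sequence and cannot be represented as FASTQ reads;
#' they are omitted here (the tag-count TSV written by [writeTagCounts()] is
#' the lossless representation). A \code{.gz} suffix triggers compression.
#'
#' @param raw a [RawTagLibrary-class].
#' @param path output FASTQ(.gz) file.
#' @return invisibly, the path.
#' @export
writeRawFastq <- function(raw, path) {
  stopifnot(is(raw, "RawTagLibrary"))
  rec <- raw@records
  rec <- rec[!is.na(rec$tag) & rec$tag != "", , drop = FALSE]
  reads <- rep.int(rec$tag, rec$count)
  x <- Biostrings::DNAStringSet(reads)
  names(x) <- sprintf("%s_%07d", raw@libraryId, seq_along(reads))
  quals <- Biostrings::BStringSet(strrep("I", nchar(reads)))
  Biostrings::writeXStringSet(x, filepath = path, format = "fastq",
                              qualities = quals,
                              compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Read a raw library from FASTQ
#' @param path FASTQ(.gz) file of tag reads.
#' @param libraryId label for the library.
#' @return a [RawTagLibrary-class] (reads aggregated to tag counts).
#' @export
readRawFastq <- function(path, libraryId = sub("\\.f(ast)?q(\\.gz)?$", "",
                                               basename(path))) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  cnt <- table(as.character(x))
  new("RawTagLibrary", libraryId = libraryId,
      records = data.frame(tag = names(cnt), count = as.integer(cnt),
                           stringsAsFactors = FALSE))
}

#' Write a virtual tag index as TSV
#' @param index a [VirtualTagIndex-class].
#' @param path output TSV (columns tag, gene_ids comma-joined, site_rank,
#'   ambiguous).
#' @return invisibly, the path.
#' @export
writeIndexTsv <- function(index, path) {
  utils::write.table(as.data.frame(index), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a gene-to-term annotation TSV
#' @param path TSV with two columns: gene id, term id (header optional,
#'   detected by the column names \code{gene}/\code{term}).
#' @return an [AnnotationSet-class].
#' @export
readAnnotation <- function(path) {
  df <- utils::read.delim(path, header = FALSE, quote = "",
                          colClasses = "character")
  if (nrow(df) && tolower(df[1L, 1L]) == "gene") df <- df[-1L, , drop = FALSE]
  annotationSet(split(df[[1L]], df[[2L]]))
}

#' Write a simulated experiment bundle to disk
#'
#' Persists a simulation as plain files: reference FASTA, per-library raw
#' tag-count TSVs and FASTQ(.gz), the ground-truth expression matrix and DE
#' labels as TSVs, per-library provenance TSVs and the configuration as
#' YAML.
#'
#' @param sim list from [simulateDGEExperiment()].
#' @param dir output directory (created if needed).
#' @param fastq also write gzipped FASTQ libraries (default FALSE; the TSVs
#'   are the canonical representation).
#' @return invisibly, the directory.
#' @export
writeSimBundle <- function(sim, dir, fastq = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeReferenceFasta(sim$genes, file.path(dir, "reference.fasta"))
  for (lib in sim$libraries) {
    writeTagCounts(lib, file.path(dir, paste0("raw_", libraryId(lib), ".tsv")))
    if (fastq)
      writeRawFastq(lib, file.path(dir, paste0("raw_", libraryId(lib), ".fastq.gz")))
  }
  truth <- sim$truth
  utils::write.table(trueExpression(truth),
                     file.path(dir, "truth_expression.tsv"),
                     sep = "\t", quote = FALSE, col.names = NA)
  utils::write.table(deTruthLabels(truth),
                     file.path(dir, "truth_de_labels.tsv"),
                     sep = "\t", quote = FALSE, col.names = NA)
  prov <- tagProvenance(truth)
  for (nm in names(prov)) {
    utils::write.table(prov[[nm]],
                       file.path(dir, paste0("truth_provenance_", nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  cfg <- sim$config
  yaml::write_yaml(list(
    nGenes = cfg@nGenes,
    transcriptLengthRange = cfg@transcriptLengthRange,
    gcContent = cfg@gcContent,
    nLibraries = cfg@nLibraries,
    baseMeanExpression = cfg@baseMeanExpression,
    deFraction = cfg@deFraction,
    deFoldChange = cfg@deFoldChange,
    depth = cfg@depth,
    errorRate = cfg@errorRate,
    adaptorOnlyRate = cfg@adaptorOnlyRate,
    nTagRate = cfg@nTagRate,
    seed = cfg@seed
  ), file.path(dir, "config.yaml"))
  invisible(dir)
}
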