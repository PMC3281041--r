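# End-to-end orchestration: clean -> index -> map -> TPM -> pairwise DE
# (-> enrichment), with a library-statistics report and an up/down summary.

#' Read a pipeline configuration from YAML
#'
#' Flat keys mirroring the arguments of [runPipeline()]; a \code{simulator}
#' block is passed to [simConfig()].
#'
#' @param path YAML file.
#' @return named list of arguments for [runPipeline()].
#' @export
readPipelineConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$simulator)) cfg$simConfig <- do.call(simConfig, cfg$simulator)
  cfg$simulator <- NULL
  cfg
}

.writeTsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full tag-DGE pipeline
#'
#' Either simulates an experiment (when \code{simConfig} is given) or loads
#' the reference FASTA plus raw tag-count TSVs, then runs: cleaning of every
#' library, virtual-tag index construction, mapping, TPM quantification,
#' Audic-Claverie differential expression for every library pair
#' (orientation: later over earlier), and, when an annotation table is
#' supplied, hypergeometric enrichment of each pair's DE gene set. All
#' intermediate tables are written as TSVs under \code{outputDir}, together
#' with a statistics report, an up/down summary and a file manifest; every
#' number in the rendered report is recomputable from the emitted TSVs.
#'
#' @param outputDir output directory (created if needed).
#' @param simConfig optional [SimConfig-class]; when given, inputs are
#'   simulated (and the truth bundle is written alongside the results).
#' @param referenceFasta path to the reference transcriptome FASTA (ignored
#'   when simulating).
#' @param rawLibraries named character vector of raw tag-count TSV paths
#'   (ignored when simulating).
#' @param genomeFasta optional genomic FASTA for the secondary 21-mer
#'   reference.
#' @param annotationTsv optional gene-to-term TSV for enrichment.
#' @param alpha,lfcThreshold,sigMode DE thresholds, see [callDEGenes()].
#' @param enrichAlpha,correction enrichment thresholds, see
#'   [enrichAllTerms()].
#' @return invisibly, a list with all in-memory intermediates
#'   (\code{stats}, \code{clean}, \code{index}, \code{mappings},
#'   \code{expression}, \code{se}, \code{de}, \code{enrichment},
#'   \code{report}).
#' @export
runPipeline <- function(outputDir,
                        simConfig = NULL,
                        referenceFasta = NULL,
                        rawLibraries = NULL,
                        genomeFasta = NULL,
                        annotationTsv = NULL,
                        alpha = 0.001, lfcThreshold = 1, sigMode = "fdr",
                        enrichAlpha = 0.05, correction = "BH") {
  dir.create(outputDir, showWarnings = FALSE, recursive = TRUE)
  logCon <- file.path(outputDir, "pipeline.log")
  logf <- function(...) {
    msg <- paste0(format(Sys.time(), "%H:%M:%S"), " ", sprintf(...))
    message(msg)
    cat(msg, "\n", file = logCon, append = TRUE)
  }
  stage <- "input"
  result <- tryCatch({
    if (!is.null(simConfig)) {
      logf("simulating experiment (%d genes, depth %d, %d libraries)",
           simConfig@nGenes, simConfig@depth, simConfig@nLibraries)
      sim <- simulateDGEExperiment(simConfig)
      writeSimBundle(sim, file.path(outputDir, "simulated_input"))
      genes <- sim$genes
      rawLibs <- sim$libraries
    } else {
      if (is.null(referenceFasta) || is.null(rawLibraries))
        stop("either 'simConfig' or both 'referenceFasta' and 'rawLibraries' are required")
      genes <- readReferenceFasta(referenceFasta)
      rawLibs <- lapply(names(rawLibraries), function(nm)
        readTagCounts(rawLibraries[[nm]], libraryId = nm))
      names(rawLibs) <- names(rawLibraries)
      sim <- NULL
    }

    stage <- "clean"
    cleaned <- lapply(rawLibs, cleanRawTags)
    for (cl in cleaned) {
      logf("cleaned %s: %d raw -> %d clean copies", libraryId(cl$clean),
           cl$stats@rawTotal, cl$stats@cleanTotal)
      .writeTsv(data.frame(tag = names(tagCounts(cl$clean)),
                           count = unname(tagCounts(cl$clean))),
                file.path(outputDir, paste0("clean_", libraryId(cl$clean), ".tsv")))
      .writeTsv(as.data.frame(cl$stats),
                file.path(outputDir, paste0("stats_", libraryId(cl$clean), ".tsv")))
    }

    stage <- "index"
    genomeKmers <- if (!is.null(genomeFasta))
      genomeTagKmers(readReferenceFasta(genomeFasta)) else character()
    index <- buildTagIndex(genes, genomeKmers)
    logf("virtual tag index: %d tags (%d ambiguous)", length(index),
         sum(index@ambiguous))
    writeIndexTsv(index, file.path(outputDir, "virtual_tag_index.tsv"))

    stage <- "map"
    mappings <- lapply(cleaned, function(cl) mapLibrary(cl$clean, index))
    for (mp in mappings) {
      t <- mappingTotals(mp)
      logf("mapped %s: gene %d | genome %d | unknown %d copies",
           libraryId(mp), t$geneAllCopies, t$genomeCopies, t$unknownCopies)
      .writeTsv(geneCounts(mp),
                file.path(outputDir, paste0("gene_counts_", libraryId(mp), ".tsv")))
    }

    stage <- "tpm"
    geneIds <- names(as.character(genes))
    expr <- mapply(function(mp, cl) expressionFromMapping(mp, cl$clean, geneIds),
                   mappings, cleaned, SIMPLIFY = FALSE)
    se <- expressionSummarizedExperiment(expr)
    exprDf <- data.frame(gene = geneIds,
                         SummarizedExperiment::assay(se, "counts"),
                         check.names = FALSE)
    tpmDf <- SummarizedExperiment::assay(se, "tpm")
    colnames(tpmDf) <- paste0("tpm_", colnames(tpmDf))
    .writeTsv(cbind(exprDf, tpmDf), file.path(outputDir, "expression.tsv"))

    stage <- "de"
    nLib <- length(expr)
    dePairs <- list()
    if (nLib >= 2L) {
      for (i in seq_len(nLib - 1L)) for (j in (i + 1L):nLib) {
        de <- callDEGenes(expr[[i]], expr[[j]], alpha = alpha,
                          lfcThreshold = lfcThreshold, sigMode = sigMode)
        key <- paste0(libraryId(expr[[i]]), "_vs_", libraryId(expr[[j]]))
        dePairs[[key]] <- de
        s <- summarizeDECalls(de)
        logf("DE %s: %d up, %d down (%d total)", key, s$up, s$down, s$total)
        .writeTsv(de, file.path(outputDir, paste0("de_", key, ".tsv")))
      }
    }

    stage <- "enrichment"
    enrich <- NULL
    if (!is.null(annotationTsv)) {
      ann <- readAnnotation(annotationTsv)
      enrich <- lapply(dePairs, function(de) {
        deg <- de$gene[de$call != "ns"]
        deg <- intersect(deg, ann@universe)
        if (!length(deg)) return(NULL)
        enrichAllTerms(ann, deg, correction = correction, alpha = enrichAlpha)
      })
      for (key in names(enrich)) {
        if (!is.null(enrich[[key]]))
          .writeTsv(enrich[[key]],
                    file.path(outputDir, paste0("enrichment_", key, ".tsv")))
      }
    }

    stage <- "report"
    report <- .renderReport(cleaned, mappings, dePairs, length(geneIds))
    writeLines(report, file.path(outputDir, "report.txt"))
    manifest <- list.files(outputDir, recursive = TRUE)
    writeLines(manifest, file.path(outputDir, "MANIFEST"))
    logf("pipeline complete: %d files under %s", length(manifest), outputDir)

    invisible(list(
      stats = lapply(cleaned, `[[`, "stats"),
      clean = lapply(cleaned, `[[`, "clean"),
      index = index, mappings = mappings, expression = expr, se = se,
      de = dePairs, enrichment = enrich, report = report,
      truth = if (!is.null(sim)) sim$truth else NULL))
  }, error = function(e) {
    stop(sprintf("pipeline failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  result
}

# Text report: one statistics block per library (counts with percentages of
# clean / distinct clean, as in conventional tag-library summary tables)
# followed by the up/down counts of every pairwise comparison.
.renderReport <- function(cleaned, mappings, dePairs, nRefGenes) {
  out <- c("Tag library statistics", "======================")
  for (nm in names(cleaned)) {
    st <- cleaned[[nm]]$stats
    t <- mappingTotals(mappings[[nm]])
    summ <- summarizeLibrary(list(
      rawTotal = st@rawTotal, distinctRaw = st@distinctRaw,
      cleanTotal = st@cleanTotal, distinctClean = st@distinctClean,
      geneAllCopies = t$geneAllCopies, geneAllDistinct = t$geneAllDistinct,
      geneUnambiguousCopies = t$geneUnambiguousCopies,
      geneUnambiguousDistinct = t$geneUnambiguousDistinct,
      genesAll = t$genesAll, genesUnambiguous = t$genesUnambiguous,
      genomeCopies = t$genomeCopies, genomeDistinct = t$genomeDistinct,
      unknownCopies = t$unknownCopies, unknownDistinct = t$unknownDistinct,
      nRefGenes = nRefGenes))
    out <- c(out, "", paste0("Library ", nm))
    out <- c(out, vapply(seq_len(nrow(summ)), function(i) {
      pc <- if (is.na(summ$percent[i])) ""
            else sprintf("  (%.2f%% of %s)", summ$percent[i], summ$percent_of[i])
      sprintf("  %-28s %12s%s", summ$metric[i],
              format(summ$count[i], big.mark = ","), pc)
    }, ""))
  }
  out <- c(out, "", "Differentially expressed genes", "==============================")
  for (key in names(dePairs)) {
    s <- summarizeDECalls(dePairs[[key]])
    out <- c(out, sprintf("  %-24s up %5d   down %5d   total %5d",
                          key, s$up, s$down, s$total))
  }
  out
}
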