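test_that("transcriptome simulation honours length contract and seed determinism", {
  cfg <- simConfig(nGenes = 1L, transcriptLengthRange = c(25L, 25L), seed = 7)
  g1 <- simulateTranscriptome(cfg)
  expect_length(g1, 1L)
  expect_equal(Biostrings::width(g1), 25L)
  g2 <- simulateTranscriptome(cfg)
  expect_identical(as.character(g1), as.character(g2))

  expect_error(simConfig(transcriptLengthRange = c(500L, 300L)), "max < min")
  expect_error(simConfig(transcriptLengthRange = c(10L, 20L)), ">= 25")
})

test_that("taggable flags agree with a brute-force window scan", {
  cfg <- simConfig(nGenes = 500L, transcriptLengthRange = c(300L, 2000L),
                   gcContent = 0.4, seed = 1)
  genes <- simulateTranscriptome(cfg)
  seqs <- as.character(genes)
  oracle <- vapply(seqs, function(s) length(bruteVirtualTags(s)) > 0L, TRUE,
                   USE.NAMES = FALSE)
  expect_identical(unname(S4Vectors::mcols(genes)$taggable), oracle)
  # at this length and GC nearly everything should carry a usable site
  expect_gt(mean(oracle), 0.9)
})

test_that("expression profiles implement the DE construction contract", {
  cfg0 <- simConfig(nGenes = 100L, deFraction = 0, seed = 5)
  genes <- simulateTranscriptome(cfg0)
  pr0 <- simulateExpressionProfiles(cfg0, genes)
  expect_true(all(pr0$deLabels == "null"))
  expect_equal(pr0$expression[, 1L], pr0$expression[, 2L])
  expect_equal(pr0$expression[, 1L], pr0$expression[, 3L])
  expect_equal(unname(colSums(pr0$expression)), rep(1, 3))

  cfg1 <- simConfig(nGenes = 100L, deFraction = 1, deFoldChange = 4,
                    nLibraries = 2L, seed = 5)
  pr1 <- simulateExpressionProfiles(cfg1, genes)
  expect_true(all(pr1$deLabels[, 1L] %in% c("up", "down")))
  # per-gene column ratio is fold or 1/fold up to the common renormalization
  ratio <- pr1$expression[, 2L] / pr1$expression[, 1L]
  scale <- exp(mean(log(range(ratio))))  # geometric midpoint of the 2 levels
  expect_equal(sort(unique(round(ratio / scale, 9))), c(0.25, 4))
  up <- pr1$deLabels[, 1L] == "up"
  expect_true(all(ratio[up] > ratio[!up][1] * 2))
})

test_that("DE gene count lands in the binomial interval implied by deFraction", {
  cfg <- simConfig(nGenes = 2000L, deFraction = 0.1, nLibraries = 2L, seed = 3)
  pr <- simulateExpressionProfiles(cfg, simulateTranscriptome(cfg))
  nDE <- sum(pr$deLabels[, 1L] != "null")
  bounds <- qbinom(c(0.005, 0.995), 2000L, 0.1)
  expect_gte(nDE, bounds[1L])
  expect_lte(nDE, bounds[2L])
})

test_that("zero-noise libraries emit exactly the 3'-most virtual tags", {
  sim <- smallSim(seed = 21, nGenes = 50L, depth = 5000L)
  seqs <- as.character(sim$genes)
  threePrime <- vapply(seqs, function(s) {
    t <- bruteVirtualTags(s)
    if (length(t)) t[1L] else NA_character_
  }, "")
  for (prov in tagProvenance(sim$truth)) {
    expect_true(all(prov$class == "gene"))
    expect_identical(prov$tag, unname(threePrime[prov$gene]))
  }
})

test_that("every emitted record carries one provenance row summing to depth", {
  sim <- smallSim(seed = 22, nGenes = 50L, depth = 3000L,
                  errorRate = 0.02, adaptorOnlyRate = 0.05, nTagRate = 0.02)
  for (l in seq_along(sim$libraries)) {
    prov <- tagProvenance(sim$truth)[[l]]
    expect_identical(nrow(prov), 3000L)
    expect_identical(sum(tagCounts(sim$libraries[[l]])$count), 3000L)
    # the aggregated records are exactly the multiset of provenance tags
    expect_identical(
      sort(rep.int(tagCounts(sim$libraries[[l]])$tag,
                   tagCounts(sim$libraries[[l]])$count)),
      sort(prov$tag))
  }
})

test_that("artifact counts match their binomial rates", {
  cfg <- simConfig(nGenes = 100L, depth = 100000L, nLibraries = 1L,
                   deFraction = 0, adaptorOnlyRate = 0.02, nTagRate = 0,
                   errorRate = 0, seed = 5)
  sim <- simulateDGEExperiment(cfg)
  nAd <- sum(tagProvenance(sim$truth)[[1L]]$class == "adaptor_only")
  bounds <- qbinom(c(0.005, 0.995), 100000L, 0.02)
  expect_gte(nAd, bounds[1L])
  expect_lte(nAd, bounds[2L])
})

test_that("noise-free tag frequencies recover the expected abundances", {
  sim <- smallSim(seed = 9, nGenes = 150L, depth = 100000L, nLibraries = 2L,
                  deFraction = 0)
  prov <- tagProvenance(sim$truth)[[1L]]
  freq <- table(factor(prov$gene, levels = rownames(trueExpression(sim$truth))))
  taggable <- S4Vectors::mcols(sim$genes)$taggable
  r <- cor(as.numeric(freq)[taggable], trueExpression(sim$truth)[taggable, 1L])
  expect_gte(r, 0.99)
})

test_that("identical configurations reproduce byte-identical experiments", {
  cfg <- simConfig(nGenes = 40L, depth = 2000L, errorRate = 0.01,
                   adaptorOnlyRate = 0.02, nTagRate = 0.01, seed = 33)
  a <- simulateDGEExperiment(cfg)
  b <- simulateDGEExperiment(cfg)
  expect_identical(as.character(a$genes), as.character(b$genes))
  expect_identical(a$profiles$expression, b$profiles$expression)
  for (l in seq_along(a$libraries))
    expect_identical(tagCounts(a$libraries[[l]]), tagCounts(b$libraries[[l]]))
})

test_that("a reference without usable CATG sites aborts tag simulation", {
  cfg <- simConfig(nGenes = 1L, transcriptLengthRange = c(30L, 30L), seed = 1)
  genes <- Biostrings::DNAStringSet(c(gene1 = strrep("A", 30L)))
  pr <- simulateExpressionProfiles(cfg, genes)
  expect_error(simulateRawTags(cfg, genes, pr), "no taggable gene")
})
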