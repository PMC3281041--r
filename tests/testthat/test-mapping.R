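refSeq <- function(tag, pad = "GG") paste0(pad, tag, pad)

test_that("single-tag mapping follows exact > one-mismatch > genome > unknown", {
  tagA <- paste0("CATG", strrep("A", 17L))
  tagC <- paste0("CATG", strrep("C", 17L))
  idx <- buildTagIndex(c(gA = refSeq(tagA), gC = refSeq(tagC)))

  hit <- mapTag(tagA, idx)
  expect_identical(hit$category, "gene_unambiguous")
  expect_identical(hit$geneIds, "gA")
  expect_identical(hit$mismatches, 0L)

  oneOff <- paste0("CATG", "T", strrep("A", 16L))
  hit1 <- mapTag(oneOff, idx)
  expect_identical(hit1$category, "gene_unambiguous")
  expect_identical(hit1$geneIds, "gA")
  expect_identical(hit1$mismatches, 1L)

  twoOff <- paste0("CATG", "TT", strrep("A", 15L))
  miss <- mapTag(twoOff, idx)
  expect_identical(miss$category, "unknown")
  expect_length(miss$geneIds, 0L)
  expect_true(is.na(miss$mismatches))

  # genome fallback, and gene precedence over genome
  idxG <- buildTagIndex(c(gA = refSeq(tagA)), genomeKmers = c(tagA, twoOff))
  expect_identical(mapTag(tagA, idxG)$category, "gene_unambiguous")
  expect_identical(mapTag(twoOff, idxG)$category, "genome")
  nearGenome <- paste0("CATG", "TTA", strrep("A", 14L))  # 1 mm from twoOff
  expect_identical(mapTag(nearGenome, idxG)$category, "genome")
})

test_that("exact unique hits are kept even when 1-mismatch neighbours exist", {
  tagA <- paste0("CATG", strrep("A", 17L))
  neighbour <- paste0("CATG", "C", strrep("A", 16L))  # 1 mm from tagA
  idx <- buildTagIndex(c(gA = refSeq(tagA), gB = refSeq(neighbour)))
  hit <- mapTag(tagA, idx)
  expect_identical(hit$category, "gene_unambiguous")
  expect_identical(hit$geneIds, "gA")
})

test_that("a tag shared by two genes is gene-mapped but not unambiguous", {
  shared <- paste0("CATG", strrep("GT", 8L), "A")
  idx <- buildTagIndex(c(g1 = refSeq(shared), g2 = refSeq(shared, "TT")))
  clean <- makeCleanTable(stats::setNames(5L, shared))
  mp <- mapLibrary(clean, idx)
  t <- mappingTotals(mp)
  expect_identical(t$geneAllDistinct, 1L)
  expect_identical(t$geneUnambiguousDistinct, 0L)
  expect_identical(t$geneAllCopies, 5L)
  expect_identical(nrow(geneCounts(mp)), 0L)
})

test_that("multi-site hits within one gene stay unambiguous", {
  tagX <- paste0("CATG", strrep("T", 17L))
  g <- paste0("AA", tagX, "CC", tagX, "GG")  # same tag at two sites
  idx <- buildTagIndex(c(gX = g))
  hit <- mapTag(tagX, idx)
  expect_identical(hit$category, "gene_unambiguous")
  expect_identical(hit$geneIds, "gX")
})

test_that("zero-noise simulated libraries map fully to genes", {
  sim <- smallSim(seed = 8, nGenes = 100L, depth = 20000L)
  idx <- buildTagIndex(sim$genes)
  clean <- cleanRawTags(sim$libraries[[1L]])$clean
  mp <- mapLibrary(clean, idx)
  t <- mappingTotals(mp)
  expect_identical(t$unknownCopies, 0L)
  expect_identical(t$genomeCopies, 0L)
  expect_identical(t$geneAllCopies + t$genomeCopies + t$unknownCopies,
                   as.integer(cleanTotal(clean)))
})

test_that("library mapping equals the brute-force Hamming oracle", {
  sim <- smallSim(seed = 15, nGenes = 100L, depth = 1000L)
  idx <- buildTagIndex(sim$genes,
                       genomeKmers = randomTags(300L, seed = 16))
  queries <- unique(c(randomTags(1500L, seed = 17),
                      sample(indexTags(idx), 100L)))
  clean <- makeCleanTable(stats::setNames(rep(2L, length(queries)), queries))
  mp <- mapLibrary(clean, idx)
  oracle <- bruteMapOracle(mp@perTag$tag, idx)
  expect_identical(mp@perTag$category, unname(oracle))
})

test_that("mapping categories partition the clean library on both bases", {
  sim <- smallSim(seed = 18, nGenes = 120L, depth = 30000L, errorRate = 0.03)
  idx <- buildTagIndex(sim$genes)
  clean <- cleanRawTags(sim$libraries[[1L]])$clean
  mp <- mapLibrary(clean, idx)
  t <- mappingTotals(mp)
  expect_identical(t$geneAllCopies + t$genomeCopies + t$unknownCopies,
                   as.integer(cleanTotal(clean)))
  expect_identical(t$geneAllDistinct + t$genomeDistinct + t$unknownDistinct,
                   t$distinctClean)
  expect_lte(t$geneUnambiguousCopies, t$geneAllCopies)
  expect_identical(sum(geneCounts(mp)$copies), as.numeric(t$geneUnambiguousCopies))
})

test_that("adding genes to the index never increases the unknown count", {
  sim <- smallSim(seed = 19, nGenes = 100L, depth = 20000L, errorRate = 0.05)
  clean <- cleanRawTags(sim$libraries[[1L]])$clean
  seqs <- as.character(sim$genes)
  half <- buildTagIndex(seqs[1:50])
  full <- buildTagIndex(seqs)
  uHalf <- mappingTotals(mapLibrary(clean, half))$unknownCopies
  uFull <- mappingTotals(mapLibrary(clean, full))$unknownCopies
  expect_lte(uFull, uHalf)
})
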