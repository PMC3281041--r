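test_that("TPM follows the per-million formula and keeps zero-count genes", {
  et <- computeTPM(c(g1 = 5, g2 = 0), cleanTotal = 1e6)
  expect_equal(unname(tpmValues(et)), c(5, 0))
  expect_identical(names(tpmValues(et)), c("g1", "g2"))
  expect_error(computeTPM(c(g1 = 1), cleanTotal = 0), "positive")
  expect_error(computeTPM(c(g1 = -1), cleanTotal = 10), "non-negative")

  # linearity: doubling counts at fixed denominator doubles TPM
  a <- computeTPM(c(g1 = 3, g2 = 7), cleanTotal = 1234)
  b <- computeTPM(c(g1 = 6, g2 = 14), cleanTotal = 1234)
  expect_equal(unname(tpmValues(b)), 2 * unname(tpmValues(a)))
})

test_that("noise-free TPM is proportional to the true abundances", {
  sim <- smallSim(seed = 23, nGenes = 150L, depth = 100000L, deFraction = 0)
  idx <- buildTagIndex(sim$genes)
  cl <- cleanRawTags(sim$libraries[[1L]])
  et <- expressionFromMapping(mapLibrary(cl$clean, idx), cl$clean,
                              names(as.character(sim$genes)))
  taggable <- S4Vectors::mcols(sim$genes)$taggable
  r <- cor(tpmValues(et)[taggable], trueExpression(sim$truth)[taggable, 1L])
  expect_gte(r, 0.99)
})

test_that("copy-number distribution bins on both bases and sums to one", {
  edges <- c(2, 5, 10, 20, 50, 100, Inf)
  allHigh <- makeCleanTable(stats::setNames(rep(200L, 4L), randomTags(4L, 1)))
  d <- expressionDistribution(allHigh, edges)
  expect_equal(d$totalFraction[d$bin == "[100,Inf)"], 1)
  expect_equal(d$distinctFraction[d$bin == "[100,Inf)"], 1)

  two <- makeCleanTable(stats::setNames(c(2L, 98L), randomTags(2L, 2)))
  d2 <- expressionDistribution(two, edges)
  expect_equal(d2$totalFraction[d2$bin == "[2,5)"], 0.02)
  expect_equal(d2$totalFraction[d2$bin == "[50,100)"], 0.98)
  expect_equal(d2$distinctFraction[d2$bin == "[2,5)"], 0.5)
  expect_equal(d2$distinctFraction[d2$bin == "[50,100)"], 0.5)

  sim <- smallSim(seed = 24, nGenes = 100L, depth = 30000L)
  clean <- cleanRawTags(sim$libraries[[1L]])$clean
  d3 <- expressionDistribution(clean, edges)
  expect_equal(sum(d3$totalFraction), 1, tolerance = 1e-9)
  expect_equal(sum(d3$distinctFraction), 1, tolerance = 1e-9)
  # brute histogram oracle
  v <- as.numeric(tagCounts(clean))
  brute <- vapply(seq_len(length(edges) - 1L), function(b)
    sum(v[v >= edges[b] & v < edges[b + 1L]]) / sum(v), 0)
  expect_equal(d3$totalFraction, brute)

  expect_error(expressionDistribution(clean, c(5, 2)), "increasing")
  d0 <- expressionDistribution(makeCleanTable(stats::setNames(integer(), character())))
  expect_true(all(d0$totalFraction == 0))
})

test_that("saturation endpoints: full size recovers the library, size 0 none", {
  sim <- smallSim(seed = 25, nGenes = 80L, depth = 20000L)
  idx <- buildTagIndex(sim$genes)
  clean <- cleanRawTags(sim$libraries[[1L]])$clean
  full <- mappingTotals(mapLibrary(clean, idx))$genesUnambiguous
  sat <- saturationCurve(clean, idx, sizes = c(0, cleanTotal(clean)), seed = 2)
  expect_equal(sat$detectedGenes[1L], 0)
  expect_equal(sat$detectedGenes[2L], full)
  expect_error(saturationCurve(clean, idx, sizes = cleanTotal(clean) + 1),
               "exceeds")
})

test_that("expression tables assemble into a SummarizedExperiment", {
  a <- computeTPM(c(g1 = 2, g2 = 4), 100, "libA")
  b <- computeTPM(c(g1 = 1, g2 = 8), 200, "libB")
  se <- expressionSummarizedExperiment(list(a, b))
  expect_identical(dim(se), c(2L, 2L))
  expect_equal(SummarizedExperiment::assay(se, "counts")["g2", "libB"], 8)
  expect_equal(SummarizedExperiment::colData(se)$cleanTotal, c(100, 200))
  bad <- computeTPM(c(g3 = 1), 10, "libC")
  expect_error(expressionSummarizedExperiment(list(a, bad)), "universe")
})
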