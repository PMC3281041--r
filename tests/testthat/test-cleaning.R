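t1 <- paste0("CATG", strrep("A", 17L))
t2 <- paste0("CATG", strrep("C", 17L))
tN <- paste0("CATG", "NCGTACGTACGTACGTA")

test_that("each cleaning rule fires on its own record class", {
  raw <- makeRawLibrary(c("", t1, tN, t2), c(1L, 3L, 2L, 1L))
  res <- cleanRawTags(raw)
  expect_identical(tagCounts(res$clean), c(CATGAAAAAAAAAAAAAAAAA = 3L))
  st <- res$stats
  expect_identical(st@rawTotal, 7)
  expect_identical(st@cleanTotal, 3)
  expect_identical(st@distinctClean, 1L)
  expect_identical(st@adaptorOnlyCopies, 1)
  expect_identical(st@nContaminatedCopies, 2)
  expect_identical(st@singletonCopies, 1)
  expect_identical(st@malformedCopies, 0)
  # distinct raw counts sequences only, artifact records excluded
  expect_identical(st@distinctRaw, 3L)
})

test_that("malformed tags are counted, reported and never silently dropped", {
  short <- "CATGAAAA"
  noAnchor <- paste0("GGGG", strrep("A", 17L))
  raw <- makeRawLibrary(c(t1, short, noAnchor), c(2L, 5L, 4L))
  res <- cleanRawTags(raw)
  expect_identical(res$stats@malformedCopies, 9)
  expect_identical(cleanTotal(res$clean), 2)
  # conservation across all buckets
  st <- res$stats
  expect_identical(st@cleanTotal + st@adaptorOnlyCopies + st@nContaminatedCopies +
                     st@singletonCopies + st@malformedCopies, st@rawTotal)
})

test_that("empty input yields empty table and all-zero statistics", {
  res <- cleanRawTags(makeRawLibrary(character(), integer()))
  expect_length(tagCounts(res$clean), 0L)
  expect_identical(res$stats@rawTotal, 0)
  expect_identical(res$stats@cleanTotal, 0)
  expect_identical(unname(res$stats@pctBreakdown), rep(0, 5L))
})

test_that("singleton status is judged on aggregated sequences", {
  # the same tag split over two copy-1 records is not a singleton
  raw <- makeRawLibrary(c(t1, t1, t2), c(1L, 1L, 1L))
  res <- cleanRawTags(raw)
  expect_identical(tagCounts(res$clean), stats::setNames(2L, t1))
  expect_identical(res$stats@singletonCopies, 1)
})

test_that("cleaning is order-invariant and conserves every raw copy", {
  sim <- smallSim(seed = 14, nGenes = 80L, depth = 20000L, errorRate = 0.02,
                  adaptorOnlyRate = 0.03, nTagRate = 0.02)
  raw <- sim$libraries[[1L]]
  res <- cleanRawTags(raw)
  st <- res$stats
  expect_identical(st@cleanTotal + st@adaptorOnlyCopies + st@nContaminatedCopies +
                     st@singletonCopies + st@malformedCopies, st@rawTotal)
  expect_true(all(tagCounts(res$clean) >= 2L))

  rec <- tagCounts(raw)
  set.seed(1)
  shuffled <- makeRawLibrary(rec$tag, rec$count)
  shuffled@records <- shuffled@records[sample(nrow(rec)), ]
  res2 <- cleanRawTags(shuffled)
  expect_identical(tagCounts(res$clean), tagCounts(res2$clean))
})

test_that("library percentage reporting rounds half-up to two decimals", {
  expect_identical(percentOf(1381410, 6037779), 22.88)
  expect_identical(percentOf(6037779, 6137521), 98.37)
  expect_identical(percentOf(7, 7), 100)
  expect_true(is.na(percentOf(3, 0)))

  rep <- summarizeLibrary(list(rawTotal = 6137521, distinctRaw = 162034,
                               cleanTotal = 6037779, distinctClean = 72774,
                               geneAllCopies = 1381410))
  expect_identical(rep$percent[rep$metric == "clean_total"], 98.37)
  expect_identical(rep$percent[rep$metric == "gene_all"], 22.88)
  expect_identical(rep$percent_of[rep$metric == "gene_all"], "clean")
})
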